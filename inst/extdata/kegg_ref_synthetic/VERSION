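snapshot_version: synthetic-2026.09
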