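id	description
EC:5.14.15.42	synthetic enzyme class annotation 1
EC:3.8.3.53	synthetic enzyme class annotation 2
EC:1.16.26.66	synthetic enzyme class annotation 3
EC:4.15.14.59	synthetic enzyme class annotation 4
EC:3.19.17.27	synthetic enzyme class annotation 5
EC:4.7.28.70	synthetic enzyme class annotation 6
EC:1.18.16.34	synthetic enzyme class annotation 7
EC:6.4.21.93	synthetic enzyme class annotation 8
EC:3.10.16.30	synthetic enzyme class annotation 9
EC:1.20.26.48	synthetic enzyme class annotation 10
EC:1.20.30.51	synthetic enzyme class annotation 11
EC:3.7.20.68	synthetic enzyme class annotation 12
EC:6.20.20.78	synthetic enzyme class annotation 13
EC:4.13.7.5	synthetic enzyme class annotation 14
EC:2.17.18.92	synthetic enzyme class annotation 15
EC:1.8.9.5	synthetic enzyme class annotation 16
EC:3.4.26.99	synthetic enzyme class annotation 17
EC:3.18.8.84	synthetic enzyme class annotation 18
EC:6.10.22.17	synthetic enzyme class annotation 19
EC:6.18.25.20	synthetic enzyme class annotation 20
EC:2.18.4.52	synthetic enzyme class annotation 21
EC:6.15.26.72	synthetic enzyme class annotation 22
EC:1.17.4.4	synthetic enzyme class annotation 23
EC:6.4.4.12	synthetic enzyme class annotation 24
EC:1.12.10.11	synthetic enzyme class annotation 25
EC:2.10.4.87	synthetic enzyme class annotation 26
EC:5.3.22.79	synthetic enzyme class annotation 27
EC:6.14.5.38	synthetic enzyme class annotation 28
EC:2.15.20.19	synthetic enzyme class annotation 29
EC:1.6.11.39	synthetic enzyme class annotation 30
EC:1.5.29.75	synthetic enzyme class annotation 31
EC:5.2.15.42	synthetic enzyme class annotation 32
EC:4.20.2.81	synthetic enzyme class annotation 33
EC:5.17.17.19	synthetic enzyme class annotation 34
EC:5.10.12.64	synthetic enzyme class annotation 35
EC:6.10.8.95	synthetic enzyme class annotation 36
EC:4.15.13.22	synthetic enzyme class annotation 37
EC:5.6.16.26	synthetic enzyme class annotation 38
EC:2.13.27.30	synthetic enzyme class annotation 39
EC:4.17.11.52	synthetic enzyme class annotation 40
EC:2.9.2.45	synthetic enzyme class annotation 41
EC:4.8.6.44	synthetic enzyme class annotation 42
EC:3.15.27.45	synthetic enzyme class annotation 43
EC:1.14.30.90	synthetic enzyme class annotation 44
EC:5.1.29.3	synthetic enzyme class annotation 45
EC:2.4.6.34	synthetic enzyme class annotation 46
EC:4.18.29.45	synthetic enzyme class annotation 47
EC:1.8.18.69	synthetic enzyme class annotation 48
EC:2.1.17.72	synthetic enzyme class annotation 49
EC:2.5.23.24	synthetic enzyme class annotation 50
EC:1.16.9.15	synthetic enzyme class annotation 51
EC:5.9.14.50	synthetic enzyme class annotation 52
EC:4.16.12.38	synthetic enzyme class annotation 53
EC:3.3.3.45	synthetic enzyme class annotation 54
EC:2.7.16.59	synthetic enzyme class annotation 55
EC:4.14.17.27	synthetic enzyme class annotation 56
EC:2.10.5.30	synthetic enzyme class annotation 57
EC:3.20.27.84	synthetic enzyme class annotation 58
EC:3.19.29.23	synthetic enzyme class annotation 59
EC:4.6.18.77	synthetic enzyme class annotation 60
EC:5.9.24.76	synthetic enzyme class annotation 61
EC:2.13.5.37	synthetic enzyme class annotation 62
EC:5.12.7.40	synthetic enzyme class annotation 63
EC:1.20.28.79	synthetic enzyme class annotation 64
EC:4.8.13.5	synthetic enzyme class annotation 65
EC:1.9.13.35	synthetic enzyme class annotation 66
EC:3.8.6.39	synthetic enzyme class annotation 67
EC:6.6.3.54	synthetic enzyme class annotation 68
EC:2.14.4.25	synthetic enzyme class annotation 69
EC:6.2.18.84	synthetic enzyme class annotation 70
EC:3.12.24.24	synthetic enzyme class annotation 71
EC:3.19.26.34	synthetic enzyme class annotation 72
EC:6.17.28.47	synthetic enzyme class annotation 73
EC:2.13.17.41	synthetic enzyme class annotation 74
EC:1.14.4.79	synthetic enzyme class annotation 75
EC:3.11.7.52	synthetic enzyme class annotation 76
EC:6.8.30.22	synthetic enzyme class annotation 77
EC:3.6.7.93	synthetic enzyme class annotation 78
EC:3.14.21.45	synthetic enzyme class annotation 79
EC:1.15.30.88	synthetic enzyme class annotation 80
EC:3.5.10.76	synthetic enzyme class annotation 81
EC:5.19.18.8	synthetic enzyme class annotation 82
EC:4.4.14.46	synthetic enzyme class annotation 83
EC:3.12.1.79	synthetic enzyme class annotation 84
EC:2.8.29.98	synthetic enzyme class annotation 85
EC:1.20.5.31	synthetic enzyme class annotation 86
EC:2.8.1.76	synthetic enzyme class annotation 87
EC:3.6.16.64	synthetic enzyme class annotation 88
EC:2.12.25.76	synthetic enzyme class annotation 89
EC:5.6.9.51	synthetic enzyme class annotation 90
EC:5.2.24.11	synthetic enzyme class annotation 91
EC:4.1.28.59	synthetic enzyme class annotation 92
EC:1.15.8.85	synthetic enzyme class annotation 93
EC:6.3.14.61	synthetic enzyme class annotation 94
EC:5.7.2.2	synthetic enzyme class annotation 95
EC:2.1.19.79	synthetic enzyme class annotation 96
EC:5.18.18.94	synthetic enzyme class annotation 97
EC:1.14.28.35	synthetic enzyme class annotation 98
EC:6.6.24.29	synthetic enzyme class annotation 99
EC:1.3.5.76	synthetic enzyme class annotation 100
EC:2.5.21.89	synthetic enzyme class annotation 101
EC:3.2.17.75	synthetic enzyme class annotation 102
EC:3.15.14.92	synthetic enzyme class annotation 103
EC:4.13.29.66	synthetic enzyme class annotation 104
EC:1.8.29.97	synthetic enzyme class annotation 105
EC:6.14.16.5	synthetic enzyme class annotation 106
EC:2.15.14.26	synthetic enzyme class annotation 107
EC:5.9.28.92	synthetic enzyme class annotation 108
EC:5.7.28.12	synthetic enzyme class annotation 109
EC:1.3.13.88	synthetic enzyme class annotation 110
EC:6.6.20.10	synthetic enzyme class annotation 111
EC:1.11.21.16	synthetic enzyme class annotation 112
EC:3.15.17.44	synthetic enzyme class annotation 113
EC:3.19.16.49	synthetic enzyme class annotation 114
EC:4.16.4.6	synthetic enzyme class annotation 115
EC:3.5.30.11	synthetic enzyme class annotation 116
EC:3.14.11.92	synthetic enzyme class annotation 117
EC:3.8.4.38	synthetic enzyme class annotation 118
EC:1.3.3.67	synthetic enzyme class annotation 119
EC:5.4.26.39	synthetic enzyme class annotation 120
EC:3.18.29.89	synthetic enzyme class annotation 121
EC:3.6.1.3	synthetic enzyme class annotation 122
EC:6.8.5.57	synthetic enzyme class annotation 123
EC:1.12.21.29	synthetic enzyme class annotation 124
EC:6.19.15.65	synthetic enzyme class annotation 125
EC:1.2.29.2	synthetic enzyme class annotation 126
EC:4.2.15.16	synthetic enzyme class annotation 127
EC:2.2.7.86	synthetic enzyme class annotation 128
EC:3.2.17.9	synthetic enzyme class annotation 129
EC:5.8.23.15	synthetic enzyme class annotation 130
EC:6.17.19.10	synthetic enzyme class annotation 131
EC:4.10.12.74	synthetic enzyme class annotation 132
EC:3.8.12.2	synthetic enzyme class annotation 133
EC:5.17.4.33	synthetic enzyme class annotation 134
EC:1.8.17.37	synthetic enzyme class annotation 135
EC:3.20.19.72	synthetic enzyme class annotation 136
EC:4.8.13.77	synthetic enzyme class annotation 137
EC:2.5.3.42	synthetic enzyme class annotation 138
EC:6.11.22.97	synthetic enzyme class annotation 139
EC:3.7.5.71	synthetic enzyme class annotation 140
EC:2.5.26.61	synthetic enzyme class annotation 141
EC:2.2.17.44	synthetic enzyme class annotation 142
EC:1.11.29.37	synthetic enzyme class annotation 143
EC:3.10.30.98	synthetic enzyme class annotation 144
EC:1.12.17.6	synthetic enzyme class annotation 145
EC:6.13.13.77	synthetic enzyme class annotation 146
EC:6.2.12.91	synthetic enzyme class annotation 147
EC:5.10.24.43	synthetic enzyme class annotation 148
EC:3.3.11.43	synthetic enzyme class annotation 149
EC:1.13.28.65	synthetic enzyme class annotation 150
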