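id	description
GLYCOLYSIS	synthetic MetaCyc pathway annotation 1
TCA	synthetic MetaCyc pathway annotation 2
CALVIN-PWY	synthetic MetaCyc pathway annotation 3
PWY-101	synthetic MetaCyc pathway annotation 4
ANAGLYCOLYSIS-PWY	synthetic MetaCyc pathway annotation 5
PWY-1005	synthetic MetaCyc pathway annotation 6
PWY-1032	synthetic MetaCyc pathway annotation 7
PWY-1087	synthetic MetaCyc pathway annotation 8
PWY-1195	synthetic MetaCyc pathway annotation 9
PWY-1268	synthetic MetaCyc pathway annotation 10
PWY-1336	synthetic MetaCyc pathway annotation 11
PWY-1387	synthetic MetaCyc pathway annotation 12
PWY-1522	synthetic MetaCyc pathway annotation 13
PWY-1566	synthetic MetaCyc pathway annotation 14
PWY-1578	synthetic MetaCyc pathway annotation 15
PWY-1585	synthetic MetaCyc pathway annotation 16
PWY-1656	synthetic MetaCyc pathway annotation 17
PWY-1679	synthetic MetaCyc pathway annotation 18
PWY-1685	synthetic MetaCyc pathway annotation 19
PWY-1699	synthetic MetaCyc pathway annotation 20
PWY-1777	synthetic MetaCyc pathway annotation 21
PWY-1793	synthetic MetaCyc pathway annotation 22
PWY-1939	synthetic MetaCyc pathway annotation 23
PWY-2040	synthetic MetaCyc pathway annotation 24
PWY-2091	synthetic MetaCyc pathway annotation 25
PWY-2118	synthetic MetaCyc pathway annotation 26
PWY-2163	synthetic MetaCyc pathway annotation 27
PWY-2197	synthetic MetaCyc pathway annotation 28
PWY-2207	synthetic MetaCyc pathway annotation 29
PWY-2208	synthetic MetaCyc pathway annotation 30
PWY-2321	synthetic MetaCyc pathway annotation 31
PWY-2422	synthetic MetaCyc pathway annotation 32
PWY-2431	synthetic MetaCyc pathway annotation 33
PWY-2565	synthetic MetaCyc pathway annotation 34
PWY-2570	synthetic MetaCyc pathway annotation 35
PWY-2605	synthetic MetaCyc pathway annotation 36
PWY-2642	synthetic MetaCyc pathway annotation 37
PWY-2650	synthetic MetaCyc pathway annotation 38
PWY-2654	synthetic MetaCyc pathway annotation 39
PWY-2665	synthetic MetaCyc pathway annotation 40
PWY-2744	synthetic MetaCyc pathway annotation 41
PWY-2756	synthetic MetaCyc pathway annotation 42
PWY-2845	synthetic MetaCyc pathway annotation 43
PWY-2875	synthetic MetaCyc pathway annotation 44
PWY-2949	synthetic MetaCyc pathway annotation 45
PWY-3060	synthetic MetaCyc pathway annotation 46
PWY-3089	synthetic MetaCyc pathway annotation 47
PWY-3128	synthetic MetaCyc pathway annotation 48
PWY-3137	synthetic MetaCyc pathway annotation 49
PWY-3162	synthetic MetaCyc pathway annotation 50
PWY-3204	synthetic MetaCyc pathway annotation 51
PWY-3267	synthetic MetaCyc pathway annotation 52
PWY-3315	synthetic MetaCyc pathway annotation 53
PWY-3519	synthetic MetaCyc pathway annotation 54
PWY-3617	synthetic MetaCyc pathway annotation 55
PWY-3630	synthetic MetaCyc pathway annotation 56
PWY-3636	synthetic MetaCyc pathway annotation 57
PWY-3661	synthetic MetaCyc pathway annotation 58
PWY-3720	synthetic MetaCyc pathway annotation 59
PWY-3729	synthetic MetaCyc pathway annotation 60
PWY-3732	synthetic MetaCyc pathway annotation 61
PWY-3764	synthetic MetaCyc pathway annotation 62
PWY-3800	synthetic MetaCyc pathway annotation 63
PWY-3813	synthetic MetaCyc pathway annotation 64
PWY-3970	synthetic MetaCyc pathway annotation 65
PWY-4153	synthetic MetaCyc pathway annotation 66
PWY-4159	synthetic MetaCyc pathway annotation 67
PWY-4255	synthetic MetaCyc pathway annotation 68
PWY-4314	synthetic MetaCyc pathway annotation 69
PWY-4327	synthetic MetaCyc pathway annotation 70
PWY-4403	synthetic MetaCyc pathway annotation 71
PWY-4419	synthetic MetaCyc pathway annotation 72
PWY-4432	synthetic MetaCyc pathway annotation 73
PWY-4566	synthetic MetaCyc pathway annotation 74
PWY-4567	synthetic MetaCyc pathway annotation 75
PWY-4608	synthetic MetaCyc pathway annotation 76
PWY-4668	synthetic MetaCyc pathway annotation 77
PWY-4689	synthetic MetaCyc pathway annotation 78
PWY-4743	synthetic MetaCyc pathway annotation 79
PWY-4779	synthetic MetaCyc pathway annotation 80
PWY-4870	synthetic MetaCyc pathway annotation 81
PWY-4985	synthetic MetaCyc pathway annotation 82
PWY-5157	synthetic MetaCyc pathway annotation 83
PWY-5181	synthetic MetaCyc pathway annotation 84
PWY-5187	synthetic MetaCyc pathway annotation 85
PWY-5251	synthetic MetaCyc pathway annotation 86
PWY-5263	synthetic MetaCyc pathway annotation 87
PWY-5319	synthetic MetaCyc pathway annotation 88
PWY-5384	synthetic MetaCyc pathway annotation 89
PWY-5421	synthetic MetaCyc pathway annotation 90
PWY-5446	synthetic MetaCyc pathway annotation 91
PWY-5526	synthetic MetaCyc pathway annotation 92
PWY-5559	synthetic MetaCyc pathway annotation 93
PWY-5683	synthetic MetaCyc pathway annotation 94
PWY-5865	synthetic MetaCyc pathway annotation 95
PWY-6100	synthetic MetaCyc pathway annotation 96
PWY-6120	synthetic MetaCyc pathway annotation 97
PWY-6200	synthetic MetaCyc pathway annotation 98
PWY-6239	synthetic MetaCyc pathway annotation 99
PWY-6322	synthetic MetaCyc pathway annotation 100
PWY-6356	synthetic MetaCyc pathway annotation 101
PWY-6385	synthetic MetaCyc pathway annotation 102
PWY-6571	synthetic MetaCyc pathway annotation 103
PWY-6756	synthetic MetaCyc pathway annotation 104
PWY-6913	synthetic MetaCyc pathway annotation 105
PWY-6958	synthetic MetaCyc pathway annotation 106
PWY-7094	synthetic MetaCyc pathway annotation 107
PWY-7217	synthetic MetaCyc pathway annotation 108
PWY-7267	synthetic MetaCyc pathway annotation 109
PWY-7340	synthetic MetaCyc pathway annotation 110
PWY-7366	synthetic MetaCyc pathway annotation 111
PWY-7399	synthetic MetaCyc pathway annotation 112
PWY-7450	synthetic MetaCyc pathway annotation 113
PWY-7451	synthetic MetaCyc pathway annotation 114
PWY-7517	synthetic MetaCyc pathway annotation 115
PWY-7601	synthetic MetaCyc pathway annotation 116
PWY-7661	synthetic MetaCyc pathway annotation 117
PWY-7675	synthetic MetaCyc pathway annotation 118
PWY-7680	synthetic MetaCyc pathway annotation 119
PWY-7694	synthetic MetaCyc pathway annotation 120
PWY-7739	synthetic MetaCyc pathway annotation 121
PWY-7741	synthetic MetaCyc pathway annotation 122
PWY-7864	synthetic MetaCyc pathway annotation 123
PWY-7880	synthetic MetaCyc pathway annotation 124
PWY-7922	synthetic MetaCyc pathway annotation 125
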