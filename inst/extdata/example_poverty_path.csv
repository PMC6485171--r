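year,target
2011,0.150
2012,0.147
2013,0.144
2014,0.141
2015,0.138
2016,0.147
2017,0.156
2018,0.166
2019,0.175
2020,0.184
2021,0.178
2022,0.171
2023,0.165
2024,0.158
2025,0.152
2026,0.146
2027,0.139
2028,0.133
2029,0.126
2030,0.120
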