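"contact_id","x_um","y_um","z_um"
1,-336.3,-1005,302.7
2,-907.6,-624.3,258.2
3,-1143.2,21.6,215.3
4,-966.1,686.8,174
5,-448.8,1142.1,134.1
6,233,1247.4,95.6
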