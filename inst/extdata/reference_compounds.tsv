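alias	formula	mz_mh	mz_mna	mz_mk	fragments	note
ART	C15H22O5	283.1537	305.1354	321.1092	265 247 229 237 219 209 205 191
de-ART	C15H22O4	267.1589	289.1407	305.1142	249 231 221 203 239
DHA	C15H24O5	285.1447	307.1509	323.1251	267 249 231 239 221 203	printed [M+H]+ inconsistent with C15H24O5 (about -25 mDa); reported by the validator, not reconciled
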