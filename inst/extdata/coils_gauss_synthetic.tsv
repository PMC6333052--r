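width	cc_mean	cc_sd	glob_mean	glob_sd
14	1.6139	0.1935	1.0963	0.2119
21	1.602	0.1646	1.0447	0.164
28	1.5895	0.1467	1.0084	0.141
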