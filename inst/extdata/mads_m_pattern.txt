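# Default M-domain detection pattern (PROSITE syntax, one pattern per line).
# Package-authored pattern for the conserved core of the plant MADS
# DNA-binding helix: the KRIEN ... RQVT[FY] ... KRR stretch shared by
# MIKC-type MADS-box proteins. Edit or replace to change stage-1 detection.
[KR]-[RK]-I-E-N-[KQR]-[IT]-[NS]-[RK]-Q-[VI]-T-[FY]-[SCA]-K-R-R.
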