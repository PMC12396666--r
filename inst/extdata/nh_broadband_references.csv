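# Synthetic normal-hearing binaural broadband categorical loudness-function
# parameters (two-branch model, pivot 25 CU). The IFnoise binaural reference
# is anchored so that it reaches 40 CU at exactly 82.3 dB SPL
# (l_cut + 15/m_hi = 82.3).
stimulus_id,l_cut_db_spl,m_lo_cu_per_db,m_hi_cu_per_db
UEN5,70.0,0.45,0.85
UEN17,66.0,0.50,0.90
IFnoise,67.3,0.50,1.00
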