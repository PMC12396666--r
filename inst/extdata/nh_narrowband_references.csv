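# Synthetic normal-hearing narrowband (critical-band noise) categorical
# loudness-function parameters, one row per audiometric frequency.
# Two-branch model pivoting at 25 CU at l_cut_db_spl; hl_to_spl_offset_db is
# the packaged RETSPL-style HL->SPL transfer value, consistent with the
# convention that the NH 2.5-CU ("very soft") point lies 2 dB above
# 0 dB HL: l_cut_db_spl - 22.5/m_lo = hl_to_spl_offset_db + 2.
# These defaults are synthetic placeholder values, versioned and overridable.
frequency_hz,l_cut_db_spl,m_lo_cu_per_db,m_hi_cu_per_db,hl_to_spl_offset_db
125,92.0,0.50,1.00,45.0
250,72.5,0.50,0.90,25.5
500,58.5,0.50,0.80,11.5
750,55.0,0.50,0.75,8.0
1000,54.0,0.50,0.72,7.0
1500,53.5,0.50,0.72,6.5
2000,56.0,0.50,0.72,9.0
3000,57.0,0.50,0.72,10.0
4000,56.5,0.50,0.72,9.5
6000,62.5,0.50,0.75,15.5
8000,60.0,0.50,0.80,13.0
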