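# Synthetic third-octave band spectrum for the International Female
# speech-shaped noise (IFnoise), shaped like a female-speech LTASS.
# rel_level_db is relative; the package renormalizes the bands at load time
# so their power sum equals the broadband overall level, i.e. band level at
# overall level L is L + rel_level_db - 10*log10(sum(10^(rel_level_db/10))).
# The same spectral shape is used at all broadband levels.
band_hz,rel_level_db
125,-14.0
160,-11.0
200,-9.0
250,-8.0
315,-8.0
400,-8.0
500,-8.5
630,-9.0
800,-10.0
1000,-11.0
1250,-12.0
1600,-13.0
2000,-14.0
2500,-15.0
3150,-16.0
4000,-17.0
5000,-19.0
6300,-21.0
8000,-23.0
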