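REM Conformation-dependent sugar restraints (SHELXL DFIX/DANG)
DANG_1 2.377 0.019 C1' C3'
DANG_1 2.391 0.019 C2' C4'
DANG_1 2.562 0.020 C3' C5'
DANG_1 2.378 0.018 C3' O4'
DANG_1 2.422 0.021 C4' O5'
DANG_1 2.342 0.016 C4' C1'
DANG_1 2.477 0.021 N9 C2'
DANG_1 2.311 0.019 N9 O4'
DANG_1 2.341 0.017 O4' C2'
DANG_1 2.410 0.019 O4' C5'
DFIX_1 1.521 0.009 C1' C2'
DFIX_1 1.454 0.009 C1' N9
DFIX_1 1.410 0.008 C1' O4'
DFIX_1 1.524 0.009 C2' C3'
DFIX_1 1.528 0.008 C3' C4'
DFIX_1 1.508 0.008 C4' C5'
DFIX_1 1.446 0.008 C4' O4'
DFIX_1 1.421 0.009 C5' O5'
DANG_2 2.357 0.019 C1' C3'
DANG_2 2.422 0.024 C1' O2'
DANG_2 2.373 0.019 C2' C4'
DANG_2 2.442 0.023 C2' O3'
DANG_2 2.447 0.023 C3' O2'
DANG_2 2.549 0.021 C3' C5'
DANG_2 2.341 0.018 C3' O4'
DANG_2 2.440 0.022 C4' O3'
DANG_2 2.342 0.016 C4' C1'
DANG_2 2.518 0.023 N1 C2'
DANG_2 2.358 0.020 N1 O4'
DANG_2 2.367 0.017 O4' C2'
DANG_2 2.412 0.021 O4' C5'
DFIX_2 1.521 0.009 C1' C2'
DFIX_2 1.481 0.010 C1' N1
DFIX_2 1.414 0.008 C1' O4'
DFIX_2 1.524 0.009 C2' C3'
DFIX_2 1.413 0.008 C2' O2'
DFIX_2 1.518 0.008 C3' C4'
DFIX_2 1.414 0.009 C3' O3'
DFIX_2 1.511 0.009 C4' C5'
DFIX_2 1.452 0.008 C4' O4'
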