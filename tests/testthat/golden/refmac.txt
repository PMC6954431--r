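# Conformation-dependent sugar restraints (REFMAC external)
# distances in Angstrom, angles in degrees
exte angle first chain A resi 1 ins . atom C1' second chain A resi 1 ins . atom C2' third chain A resi 1 ins . atom C3' value 102.65 sigma 1.00
exte angle first chain A resi 1 ins . atom C1' second chain A resi 1 ins . atom N9 third chain A resi 1 ins . atom C4 value 125.37 sigma 1.40
exte angle first chain A resi 1 ins . atom C1' second chain A resi 1 ins . atom N9 third chain A resi 1 ins . atom C8 value 126.05 sigma 1.30
exte angle first chain A resi 1 ins . atom C2' second chain A resi 1 ins . atom C3' third chain A resi 1 ins . atom C4' value 103.16 sigma 1.00
exte angle first chain A resi 1 ins . atom C2' second chain A resi 1 ins . atom C3' third chain A resi 1 ins . atom O3' value 109.80 sigma 1.30
exte angle first chain A resi 1 ins . atom C3' second chain A resi 1 ins . atom C4' third chain A resi 1 ins . atom C5' value 115.10 sigma 1.20
exte angle first chain A resi 1 ins . atom C3' second chain A resi 1 ins . atom C4' third chain A resi 1 ins . atom O4' value 106.17 sigma 1.00
exte angle first chain A resi 1 ins . atom C4' second chain A resi 1 ins . atom C3' third chain A resi 1 ins . atom O3' value 110.40 sigma 1.30
exte angle first chain A resi 1 ins . atom C4' second chain A resi 1 ins . atom C5' third chain A resi 1 ins . atom O5' value 111.50 sigma 1.30
exte angle first chain A resi 1 ins . atom C4' second chain A resi 1 ins . atom O4' third chain A resi 1 ins . atom C1' value 110.18 sigma 0.90
exte angle first chain A resi 1 ins . atom N9 second chain A resi 1 ins . atom C1' third chain A resi 1 ins . atom C2' value 112.76 sigma 1.30
exte angle first chain A resi 1 ins . atom N9 second chain A resi 1 ins . atom C1' third chain A resi 1 ins . atom O4' value 107.61 sigma 1.10
exte angle first chain A resi 1 ins . atom O4' second chain A resi 1 ins . atom C1' third chain A resi 1 ins . atom C2' value 105.94 sigma 0.90
exte angle first chain A resi 1 ins . atom O4' second chain A resi 1 ins . atom C4' third chain A resi 1 ins . atom C5' value 109.30 sigma 1.10
exte dist first chain A resi 1 ins . atom C1' second chain A resi 1 ins . atom C2' value 1.521 sigma 0.009
exte dist first chain A resi 1 ins . atom C1' second chain A resi 1 ins . atom N9 value 1.454 sigma 0.009
exte dist first chain A resi 1 ins . atom C1' second chain A resi 1 ins . atom O4' value 1.410 sigma 0.008
exte dist first chain A resi 1 ins . atom C2' second chain A resi 1 ins . atom C3' value 1.524 sigma 0.009
exte dist first chain A resi 1 ins . atom C3' second chain A resi 1 ins . atom C4' value 1.528 sigma 0.008
exte dist first chain A resi 1 ins . atom C4' second chain A resi 1 ins . atom C5' value 1.508 sigma 0.008
exte dist first chain A resi 1 ins . atom C4' second chain A resi 1 ins . atom O4' value 1.446 sigma 0.008
exte dist first chain A resi 1 ins . atom C5' second chain A resi 1 ins . atom O5' value 1.421 sigma 0.009
exte angle first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom C2' third chain A resi 2 ins . atom C3' value 101.43 sigma 1.00
exte angle first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom C2' third chain A resi 2 ins . atom O2' value 111.20 sigma 1.50
exte angle first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom N1 third chain A resi 2 ins . atom C2 value 119.00 sigma 1.40
exte angle first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom N1 third chain A resi 2 ins . atom C6 value 121.77 sigma 1.30
exte angle first chain A resi 2 ins . atom C2' second chain A resi 2 ins . atom C3' third chain A resi 2 ins . atom C4' value 102.51 sigma 1.00
exte angle first chain A resi 2 ins . atom C2' second chain A resi 2 ins . atom C3' third chain A resi 2 ins . atom O3' value 112.40 sigma 1.40
exte angle first chain A resi 2 ins . atom C3' second chain A resi 2 ins . atom C2' third chain A resi 2 ins . atom O2' value 112.80 sigma 1.50
exte angle first chain A resi 2 ins . atom C3' second chain A resi 2 ins . atom C4' third chain A resi 2 ins . atom C5' value 114.60 sigma 1.30
exte angle first chain A resi 2 ins . atom C3' second chain A resi 2 ins . atom C4' third chain A resi 2 ins . atom O4' value 103.99 sigma 1.00
exte angle first chain A resi 2 ins . atom C4' second chain A resi 2 ins . atom C3' third chain A resi 2 ins . atom O3' value 112.60 sigma 1.40
exte angle first chain A resi 2 ins . atom C4' second chain A resi 2 ins . atom C5' third chain A resi 2 ins . atom O5' value 111.20 sigma 1.70
exte angle first chain A resi 2 ins . atom C4' second chain A resi 2 ins . atom O4' third chain A resi 2 ins . atom C1' value 109.58 sigma 0.90
exte angle first chain A resi 2 ins . atom N1 second chain A resi 2 ins . atom C1' third chain A resi 2 ins . atom C2' value 114.02 sigma 1.40
exte angle first chain A resi 2 ins . atom N1 second chain A resi 2 ins . atom C1' third chain A resi 2 ins . atom O4' value 109.10 sigma 1.20
exte angle first chain A resi 2 ins . atom O4' second chain A resi 2 ins . atom C1' third chain A resi 2 ins . atom C2' value 107.45 sigma 0.90
exte angle first chain A resi 2 ins . atom O4' second chain A resi 2 ins . atom C4' third chain A resi 2 ins . atom C5' value 109.00 sigma 1.20
exte dist first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom C2' value 1.521 sigma 0.009
exte dist first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom N1 value 1.481 sigma 0.010
exte dist first chain A resi 2 ins . atom C1' second chain A resi 2 ins . atom O4' value 1.414 sigma 0.008
exte dist first chain A resi 2 ins . atom C2' second chain A resi 2 ins . atom C3' value 1.524 sigma 0.009
exte dist first chain A resi 2 ins . atom C2' second chain A resi 2 ins . atom O2' value 1.413 sigma 0.008
exte dist first chain A resi 2 ins . atom C3' second chain A resi 2 ins . atom C4' value 1.518 sigma 0.008
exte dist first chain A resi 2 ins . atom C3' second chain A resi 2 ins . atom O3' value 1.414 sigma 0.009
exte dist first chain A resi 2 ins . atom C4' second chain A resi 2 ins . atom C5' value 1.511 sigma 0.009
exte dist first chain A resi 2 ins . atom C4' second chain A resi 2 ins . atom O4' value 1.452 sigma 0.008
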