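data_synthetic_shifts

# Synthetic NMR-STAR 3.1 chemical-shift fragment for reader tests.
# Values are random-coil references plus small offsets; they do not
# correspond to any deposited entry.

save_assigned_chemical_shifts
   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts
   _Assigned_chem_shift_list.ID            1

   loop_
      _Atom_chem_shift.ID
      _Atom_chem_shift.Seq_ID
      _Atom_chem_shift.Comp_ID
      _Atom_chem_shift.Atom_ID
      _Atom_chem_shift.Atom_type
      _Atom_chem_shift.Val
      _Atom_chem_shift.Val_err

      1 275 VAL CA C 61.10 0.05
      2 275 VAL C  C 175.60 0.05
      3 276 GLN CA C 55.90 0.05
      4 276 GLN C  C 175.30 0.05
      5 277 ILE CA C 60.40 0.05
      6 277 ILE C  C 175.70 0.05
      7 277 ILE CB C 38.20 0.05
      8 278 ILE N  N 121.40 0.10
      9 278 ILE CA C 60.50 0.05
     10 278 ILE C  C 175.80 0.05

   stop_

save_
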