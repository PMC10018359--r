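# Example component registry. Masses in g/mol, vbar in ml/g, extinction
# coefficients in M^-1 cm^-1 keyed by wavelength (nm). A record with a
# `sequence` and no `molar_mass` gets its mass from the residue tables.
components:
  - name: RecO
    kind: protein
    molar_mass: 26964
    vbar: 0.734
    extinction: {280: 24400}
  - name: RecR
    kind: protein
    molar_mass: 21925
    vbar: 0.711
    extinction: {280: 5960}
  - name: SSB_Ct
    kind: peptide
    vbar: 0.704
    sequence: PSNEPPMDFDDDIPF
    extinction: {258: 390}
  - name: Cy3_dT15
    kind: ssDNA
    molar_mass: 5008
    vbar: 0.56
    extinction: {260: 121500}
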