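# Six-sterol panel for Oviductus Ranae quality control.
# Retention times (and hence expected RTTs) are synthetic: they follow the
# published elution order but the absolute values are invented for simulation.
reference: cholesterol
reference_window: [10.2, 12.2]
analytes:
  - name: 7-hydroxycholesterol
    wavelength: 205
    expected_rtt: 0.4107
    stock: 157.9
  - name: 7-ketocholesterol
    wavelength: 240
    expected_rtt: 0.5446
    stock: 32.525
  - name: 4-cholesten-3-one
    wavelength: 240
    expected_rtt: 0.7054
    stock: 20.225
  - name: 7-dehydrocholesterol
    wavelength: 280
    expected_rtt: 0.8393
    stock: 9.775
  - name: cholesterol
    wavelength: 205
    expected_rtt: 1.0
    stock: 4000
  - name: stigmasterol
    wavelength: 205
    expected_rtt: 1.2143
    stock: 25.738
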