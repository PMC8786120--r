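emission_factors_synthetic.csv

SYNTHETIC emission factor table (kg pollutant per tonne of waste treated,
by technology x pollutant x compartment). These numbers are invented for
testing and examples: they reproduce only the qualitative structure of the
two disposal technologies (steam sterilization dominating wastewater and
residue releases; incineration dominating most exhaust gases; hydrogen
chloride the largest gas factor; nickel the largest and lead the smallest
metal; chloride the largest residue species; ammonia/mercury/phenol/chromium
larger for steam in air). Replace with literature values for any real
assessment.
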