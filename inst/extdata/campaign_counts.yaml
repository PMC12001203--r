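# campaign funnel counts: syntheses attempted, LCMS-confirmed products,
# usable diffraction datasets after soaking, product-bound structures
attempted: 1876
lcms_success: 1077
datasets_usable: 969
product_bound: 22
starting_material_bound: 7
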