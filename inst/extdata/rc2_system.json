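{"high_reservoir":{"height_m":0.1,"density_kg_m3":1000,"concentration_norm":1,"label":"high-pressure analyte"},"low_reservoir":{"height_m":0.05,"density_kg_m3":1000,"concentration_norm":1,"label":"low-pressure analyte"},"buffer_reservoir":{"height_m":0.05,"density_kg_m3":1000,"concentration_norm":0,"label":"buffer"},"filter_resistor":{"resistance_pa_s_per_m3":21808143547274,"label":"RC2"},"filter_capacitor":{"capacitance_m3_per_pa":1.449e-14,"cavity_diameter_m":0.002,"label":"RC2"},"buffer_resistor":{"resistance_pa_s_per_m3":21808143547274,"label":"resistor chip"},"withdrawal_rate_m3_per_s":2.5e-11,"constants":{"g_m_per_s2":9.81,"viscosity_pa_s":0.001},"mixer":{"kind":"herringbone","cycles":3,"length_m":0.0069,"width_m":0.0002,"depth_m":0.0002,"molecular_diffusivity_m2_per_s":4.25e-10,"mixing_enhancement":1.8}}
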