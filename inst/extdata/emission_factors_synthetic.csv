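technology,pollutant,compartment,kg_per_tonne
incineration,hydrogen_chloride,air,3.2
steam,hydrogen_chloride,air,1.1
incineration,sulfur_dioxide,air,0.9
steam,sulfur_dioxide,air,1.2
incineration,nitrogen_oxides,air,1.8
steam,nitrogen_oxides,air,0.4
incineration,carbon_monoxide,air,1.2
steam,carbon_monoxide,air,0.25
incineration,hydrogen_fluoride,air,0.08
steam,hydrogen_fluoride,air,0.02
incineration,ammonia,air,0.05
steam,ammonia,air,0.4
incineration,mercury,air,0.0004
steam,mercury,air,0.0011
incineration,phenol,air,0.002
steam,phenol,air,0.006
incineration,chromium,air,0.0008
steam,chromium,air,0.0019
incineration,nickel,air,0.016
steam,nickel,air,0.004
incineration,copper,air,0.009
steam,copper,air,0.002
incineration,tin,air,0.005
steam,tin,air,0.0012
incineration,lead,air,0.0003
steam,lead,air,0.00008
incineration,dioxins,air,0.000002
steam,dioxins,air,0.0000001
incineration,chloride,wastewater,0.6
steam,chloride,wastewater,2.4
incineration,fluoride,wastewater,0.05
steam,fluoride,wastewater,0.21
incineration,sulfate,wastewater,0.3
steam,sulfate,wastewater,1.1
incineration,mercury,wastewater,0.00005
steam,mercury,wastewater,0.0003
incineration,cod,wastewater,0.8
steam,cod,wastewater,3.0
incineration,chloride,residue,4.0
steam,chloride,residue,9.5
incineration,fluoride,residue,0.2
steam,fluoride,residue,0.7
incineration,sulfate,residue,0.9
steam,sulfate,residue,2.2
incineration,heavy_metals,residue,0.05
steam,heavy_metals,residue,0.15
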