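name,formula,class,default_loq_pptv
isoprene,C5H8,isoprene,2
alpha-pinene,C10H16,monoterpene,2
beta-pinene,C10H16,monoterpene,2
camphene,C10H16,monoterpene,2
sabinene,C10H16,monoterpene,2
limonene,C10H16,monoterpene,2
3-carene,C10H16,monoterpene,2
p-cymene,C10H14,aromatic monoterpenoid,2
1-8-cineole,C10H18O,oxygenated monoterpenoid,2
isocaryophyllene,C15H24,sesquiterpene,2
beta-caryophyllene,C15H24,sesquiterpene,2
methacrolein,C4H6O,isoprene oxidation product,2
methyl-vinyl-ketone,C4H6O,isoprene oxidation product,2
acetonitrile,C2H3N,biomass burning tracer,2
toluene,C7H8,internal standard,2
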