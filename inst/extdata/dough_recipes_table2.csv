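dough,ingredient,mass_g,role
D_Ref,wheat_flour,86.6,flour
D_Ref,gluten,2.9,gluten
D_Ref,salt,1.5,excluded
D_Ref,dry_yeast,1.0,excluded
D_Ref,dextrose,2.0,solute
D_Ref,oil,5.9,excluded
D_Ref,added_water,43.6,water
D_FOS,wheat_flour,78.8,flour
D_FOS,gluten,2.9,gluten
D_FOS,salt,1.5,excluded
D_FOS,dry_yeast,1.0,excluded
D_FOS,dextrose,2.0,solute
D_FOS,oil,5.9,excluded
D_FOS,FOS,7.8,solute
D_FOS,added_water,35.1,water
D_Myl,wheat_flour,78.8,flour
D_Myl,gluten,2.9,gluten
D_Myl,salt,1.5,excluded
D_Myl,dry_yeast,1.0,excluded
D_Myl,dextrose,2.0,solute
D_Myl,oil,5.9,excluded
D_Myl,Myl,7.8,solute
D_Myl,added_water,36.4,water
D_OFP,wheat_flour,78.8,flour
D_OFP,gluten,2.9,gluten
D_OFP,salt,1.5,excluded
D_OFP,dry_yeast,1.0,excluded
D_OFP,dextrose,2.0,solute
D_OFP,oil,5.9,excluded
D_OFP,OFP,7.8,solute
D_OFP,added_water,35.0,water
D_Myl_PDX,wheat_flour,78.8,flour
D_Myl_PDX,gluten,2.9,gluten
D_Myl_PDX,salt,1.5,excluded
D_Myl_PDX,dry_yeast,1.0,excluded
D_Myl_PDX,dextrose,2.0,solute
D_Myl_PDX,oil,5.9,excluded
D_Myl_PDX,Myl,3.9,solute
D_Myl_PDX,PDX,3.9,solute
D_Myl_PDX,added_water,35.0,water
D_CLR,wheat_flour,78.8,flour
D_CLR,gluten,2.9,gluten
D_CLR,salt,1.5,excluded
D_CLR,dry_yeast,1.0,excluded
D_CLR,dextrose,2.0,solute
D_CLR,oil,5.9,excluded
D_CLR,CLR,7.8,solute
D_CLR,added_water,33.8,water
D_PDX,wheat_flour,78.8,flour
D_PDX,gluten,2.9,gluten
D_PDX,salt,1.5,excluded
D_PDX,dry_yeast,1.0,excluded
D_PDX,dextrose,2.0,solute
D_PDX,oil,5.9,excluded
D_PDX,PDX,7.8,solute
D_PDX,added_water,33.5,water
D_IQ,wheat_flour,78.8,flour
D_IQ,gluten,2.9,gluten
D_IQ,salt,1.5,excluded
D_IQ,dry_yeast,1.0,excluded
D_IQ,dextrose,2.0,solute
D_IQ,oil,5.9,excluded
D_IQ,IQ,7.8,solute
D_IQ,added_water,33.8,water
D_OFP_CLR,wheat_flour,78.8,flour
D_OFP_CLR,gluten,2.9,gluten
D_OFP_CLR,salt,1.5,excluded
D_OFP_CLR,dry_yeast,1.0,excluded
D_OFP_CLR,dextrose,2.0,solute
D_OFP_CLR,oil,5.9,excluded
D_OFP_CLR,OFP,5.3,solute
D_OFP_CLR,CLR,2.5,solute
D_OFP_CLR,added_water,33.9,water
D_OFP_TEX,wheat_flour,78.8,flour
D_OFP_TEX,gluten,2.9,gluten
D_OFP_TEX,salt,1.5,excluded
D_OFP_TEX,dry_yeast,1.0,excluded
D_OFP_TEX,dextrose,2.0,solute
D_OFP_TEX,oil,5.9,excluded
D_OFP_TEX,OFP,2.7,solute
D_OFP_TEX,TEX,5.1,solute
D_OFP_TEX,added_water,39.4,water
D_CLR_TEX,wheat_flour,78.8,flour
D_CLR_TEX,gluten,2.9,gluten
D_CLR_TEX,salt,1.5,excluded
D_CLR_TEX,dry_yeast,1.0,excluded
D_CLR_TEX,dextrose,2.0,solute
D_CLR_TEX,oil,5.9,excluded
D_CLR_TEX,CLR,1.9,solute
D_CLR_TEX,TEX,5.8,solute
D_CLR_TEX,added_water,39.6,water
D_TEX,wheat_flour,78.8,flour
D_TEX,gluten,2.9,gluten
D_TEX,salt,1.5,excluded
D_TEX,dry_yeast,1.0,excluded
D_TEX,dextrose,2.0,solute
D_TEX,oil,5.9,excluded
D_TEX,TEX,7.8,solute
D_TEX,added_water,41.6,water
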