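chem_class,c_min,c_max,kind,value,intensity_class,mechanism,requires_flag
phenol,,,transform,M+H,base,proton transfer,
ketone,,,transform,M+H,base,proton transfer,
aldehyde_unsaturated,,,transform,M+H,base,proton transfer,
acid,,,transform,M+H,base,proton transfer,
aromatic,,,transform,M+H,base,proton transfer,
aldehyde_saturated,,4,transform,M+H,base,proton transfer,
aldehyde_saturated,5,,transform,M-17,base,OH loss,
aldehyde_saturated,5,,transform,M-73,major,inductive cleavage,
aldehyde_saturated,5,,transform,M+H,minor,proton transfer,
alcohol_primary,,3,transform,M-H,base,hydride abstraction,
alcohol_primary,4,,transform,M-17,base,OH loss,
alcohol_primary,4,,transform,M-H,major,hydride abstraction,
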