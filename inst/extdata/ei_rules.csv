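chem_class,c_min,c_max,kind,value,intensity_class,mechanism,requires_flag
ketone,,,fixed,43,base,alpha-cleavage,
ketone,,,transform,M,minor,molecular ion,
aldehyde_saturated,4,,fixed,43,major,alpha-cleavage,
aldehyde_saturated,4,,fixed,44,major,McLafferty,
aldehyde_saturated,4,,transform,M,absent,molecular ion suppressed,
aldehyde_saturated,,3,transform,M,major,molecular ion,
aldehyde_saturated,,3,transform,M-29,major,HC=O loss,
aldehyde_unsaturated,,3,transform,M,major,molecular ion,
aldehyde_unsaturated,,3,transform,M-29,major,HC=O loss,
aldehyde_unsaturated,4,,fixed,41,base,beta-cleavage,
acid,,3,transform,M,major,molecular ion,
acid,,3,transform,M-17,major,OH loss,
acid,4,,fixed,60,base,McLafferty,
acid,4,,acylium,,major,acylium series CnH2n-1O2,
alcohol_primary,,,transform,M-18,major,water loss,
alcohol_primary,,,transform,M-33,major,H2O+CH3 loss,
alcohol_primary,,,fixed,31,major,oxocarbenium H2C=OH+,
alcohol_primary,,,transform,M-H,major,hydride loss,
phenol,,,transform,M,base,molecular ion,
phenol,,,fixed,77,major,phenyl cation,substituted
aromatic,,,transform,M,base,molecular ion,
aromatic,,,fixed,77,major,phenyl cation,substituted
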