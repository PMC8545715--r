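sample,group,total_porosity,largest_pore_fraction,largest_pore_volume_mm3,largest_pore_sa_v,sphere_equiv_sa_v
SWP550-1,SWP550,0.577,0.9993,0.408,0.242,0.00567
SWP550-2,SWP550,0.582,0.9991,0.411,0.220,0.00566
SWP700-1,SWP700,0.565,0.9992,0.399,0.231,0.00572
SWP700-2,SWP700,0.582,0.9994,0.411,0.235,0.00566
SWP700-3,SWP700,0.578,0.9992,0.408,0.225,0.00567
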