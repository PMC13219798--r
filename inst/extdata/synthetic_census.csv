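"sample_id","taxon","count","n_fov","fov_area","deposition_area","sediment_mass"
"S01","small Gephyrocapsa",136,293,0.02,1000,5e-04
"S01","large Gephyrocapsa",2,293,0.02,1000,5e-04
"S01","Helicosphaera spp.",0,293,0.02,1000,5e-04
"S01","Calcidiscus spp.",1,293,0.02,1000,5e-04
"S01","Coccolithus pelagicus",181,293,0.02,1000,5e-04
"S02","small Gephyrocapsa",252,130,0.02,1000,5e-04
"S02","large Gephyrocapsa",16,130,0.02,1000,5e-04
"S02","Helicosphaera spp.",3,130,0.02,1000,5e-04
"S02","Calcidiscus spp.",5,130,0.02,1000,5e-04
"S02","Coccolithus pelagicus",44,130,0.02,1000,5e-04
"S03","small Gephyrocapsa",265,94,0.02,1000,5e-04
"S03","large Gephyrocapsa",49,94,0.02,1000,5e-04
"S03","Helicosphaera spp.",1,94,0.02,1000,5e-04
"S03","Calcidiscus spp.",2,94,0.02,1000,5e-04
"S03","Coccolithus pelagicus",3,94,0.02,1000,5e-04
"S04","small Gephyrocapsa",238,136,0.02,1000,5e-04
"S04","large Gephyrocapsa",79,136,0.02,1000,5e-04
"S04","Helicosphaera spp.",2,136,0.02,1000,5e-04
"S04","Calcidiscus spp.",1,136,0.02,1000,5e-04
"S04","Coccolithus pelagicus",0,136,0.02,1000,5e-04
"S05","small Gephyrocapsa",246,204,0.02,1000,5e-04
"S05","large Gephyrocapsa",73,204,0.02,1000,5e-04
"S05","Helicosphaera spp.",1,204,0.02,1000,5e-04
"S05","Calcidiscus spp.",0,204,0.02,1000,5e-04
"S05","Coccolithus pelagicus",0,204,0.02,1000,5e-04
"S06","small Gephyrocapsa",230,318,0.02,1000,5e-04
"S06","large Gephyrocapsa",89,318,0.02,1000,5e-04
"S06","Helicosphaera spp.",0,318,0.02,1000,5e-04
"S06","Calcidiscus spp.",0,318,0.02,1000,5e-04
"S06","Coccolithus pelagicus",1,318,0.02,1000,5e-04
"S07","small Gephyrocapsa",235,231,0.02,1000,5e-04
"S07","large Gephyrocapsa",85,231,0.02,1000,5e-04
"S07","Helicosphaera spp.",0,231,0.02,1000,5e-04
"S07","Calcidiscus spp.",0,231,0.02,1000,5e-04
"S07","Coccolithus pelagicus",0,231,0.02,1000,5e-04
"S08","small Gephyrocapsa",246,225,0.02,1000,5e-04
"S08","large Gephyrocapsa",73,225,0.02,1000,5e-04
"S08","Helicosphaera spp.",1,225,0.02,1000,5e-04
"S08","Calcidiscus spp.",0,225,0.02,1000,5e-04
"S08","Coccolithus pelagicus",0,225,0.02,1000,5e-04
"S09","small Gephyrocapsa",264,105,0.02,1000,5e-04
"S09","large Gephyrocapsa",52,105,0.02,1000,5e-04
"S09","Helicosphaera spp.",2,105,0.02,1000,5e-04
"S09","Calcidiscus spp.",2,105,0.02,1000,5e-04
"S09","Coccolithus pelagicus",0,105,0.02,1000,5e-04
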