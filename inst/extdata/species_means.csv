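species,site,mean_d15N,mean_d13C
Ctenotus calurus,Yamarna,6.26,-17.42
Ctenotus dux,Yamarna,8.23,-18.47
Ctenotus grandis,Yamarna,9.4,-17.96
Ctenotus inornatus,Yamarna,10.09,-19.24
Ctenotus leae,Yamarna,8.47,-22.54
Ctenotus pantherinus,Yamarna,7.02,-15.86
Ctenotus piankai,Yamarna,8.78,-17.42
Ctenotus quattuordecimlineatus,Yamarna,9.42,-18.59
Ctenotus brooksi,Yamarna,9.56,-21.75
Eremiascincus fasciolatus,Yamarna,7.77,-20.56
Lerista bipes,Yamarna,7.62,-18.79
Lerista desertorum,Yamarna,11.61,-22.25
Ctenotus calurus,Lorna Glen,8.77,-17.33
Ctenotus dux,Lorna Glen,10.22,-21.46
Ctenotus inornatus,Lorna Glen,10.02,-18.10
Ctenotus leonhardii,Lorna Glen,12.91,-19.28
Ctenotus pantherinus,Lorna Glen,9.51,-16.85
Ctenotus quattuordecimlineatus,Lorna Glen,13.09,-18.30
Ctenotus schomburgkii,Lorna Glen,15.48,-20.03
Lerista bipes,Lorna Glen,7.88,-19.98
Lerista desertorum,Lorna Glen,12.39,-19.85
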