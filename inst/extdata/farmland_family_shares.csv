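bee_species,level,taxon,share_pct
Andrena alfkenella,family,API,97.0
Andrena alfkenella,family,other,3.0
Andrena bicolor,family,AST,29.6
Andrena bicolor,family,BRA,21.4
Andrena bicolor,family,CUC,13.7
Andrena bicolor,family,API,13.7
Andrena bicolor,family,CAM,10.5
Andrena bicolor,family,LIL,7.8
Andrena bicolor,family,other,3.3
Andrena chrysosceles,family,API,45.6
Andrena chrysosceles,family,BRA,32.1
Andrena chrysosceles,family,ROS,14.9
Andrena chrysosceles,family,MAL,3.1
Andrena chrysosceles,family,AST,2.2
Andrena chrysosceles,family,other,2.1
Andrena cineraria,family,BRA,53.8
Andrena cineraria,family,API,27.9
Andrena cineraria,family,ROS,12.9
Andrena cineraria,family,RHA,3.2
Andrena cineraria,family,other,2.2
Andrena dorsata,family,ROS,66.6
Andrena dorsata,family,API,11.8
Andrena dorsata,family,BRA,9.7
Andrena dorsata,family,AST,7.3
Andrena dorsata,family,FAB,4.7
Andrena flavipes,family,AST,56.0
Andrena flavipes,family,BRA,20.1
Andrena flavipes,family,FAB,10.5
Andrena flavipes,family,ROS,5.1
Andrena flavipes,family,API,5.0
Andrena flavipes,family,other,3.3
Andrena florea,family,CUC,100.0
Andrena florea,genus,Bryonia,100.0
Andrena haemorrhoa,family,ROS,37.8
Andrena haemorrhoa,family,BRA,31.5
Andrena haemorrhoa,family,AST,14.7
Andrena haemorrhoa,family,RES,6.3
Andrena haemorrhoa,family,CAP,4.9
Andrena haemorrhoa,family,other,4.8
Andrena labiata,family,CAR,50.0
Andrena labiata,family,VER,16.7
Andrena labiata,family,RAN,12.5
Andrena labiata,family,BRA,10.8
Andrena labiata,family,AST,7.5
Andrena labiata,family,GER,2.5
Andrena minutula,family,API,56.4
Andrena minutula,family,BRA,23.6
Andrena minutula,family,ROS,11.6
Andrena minutula,family,AST,8.0
Andrena minutula,family,other,0.4
Andrena minutuloides,family,API,100.0
Andrena nigroaenea,family,API,39.4
Andrena nigroaenea,family,AST,34.5
Andrena nigroaenea,family,BRA,14.2
Andrena nigroaenea,family,RAN,6.3
Andrena nigroaenea,family,RES,3.1
Andrena nigroaenea,family,other,2.5
Andrena nitida,family,BRA,45.6
Andrena nitida,family,API,16.3
Andrena nitida,family,ACE,9.9
Andrena nitida,family,RHA,9.1
Andrena nitida,family,AST,4.7
Andrena nitida,family,SOL,3.8
Andrena nitida,family,LAM,3.8
Andrena nitida,family,ROS,2.4
Andrena nitida,family,other,4.5
Andrena scotica,family,BRA,65.7
Andrena scotica,family,ACE,19.6
Andrena scotica,family,API,5.4
Andrena scotica,family,ROS,4.2
Andrena scotica,family,other,5.1
Andrena semilaevis,family,API,91.3
Andrena semilaevis,family,BRA,5.3
Andrena semilaevis,family,VER,1.9
Andrena semilaevis,family,other,1.5
Andrena subopaca,family,API,48.4
Andrena subopaca,family,BRA,19.3
Andrena subopaca,family,ROS,18.2
Andrena subopaca,family,VER,9.2
Andrena subopaca,family,FAB,2.6
Andrena subopaca,family,other,2.3
Halictus tumulorum,family,AST,24.2
Halictus tumulorum,family,RAN,22.2
Halictus tumulorum,family,FAB,16.9
Halictus tumulorum,family,ROS,13.9
Halictus tumulorum,family,BRA,12.4
Halictus tumulorum,family,RUB,6.8
Halictus tumulorum,family,LIL,3.0
Halictus tumulorum,family,other,0.6
Lasioglossum albipes,family,RAN,65.3
Lasioglossum albipes,family,ROS,33.3
Lasioglossum albipes,family,other,1.4
Lasioglossum calceatum,family,AST,46.9
Lasioglossum calceatum,family,BRA,17.5
Lasioglossum calceatum,family,ROS,11.3
Lasioglossum calceatum,family,API,6.0
Lasioglossum calceatum,family,LAM,3.9
Lasioglossum calceatum,family,BER,3.7
Lasioglossum calceatum,family,OLE,3.5
Lasioglossum calceatum,family,RAN,2.6
Lasioglossum calceatum,family,other,4.6
Lasioglossum fulvicorne,family,BRA,67.2
Lasioglossum fulvicorne,family,ROS,26.9
Lasioglossum fulvicorne,family,API,5.0
Lasioglossum fulvicorne,family,other,0.8
Lasioglossum lativentre,family,FAB,95.3
Lasioglossum lativentre,family,RAN,2.6
Lasioglossum lativentre,family,AST,2.1
Lasioglossum leucopus,family,BRA,68.1
Lasioglossum leucopus,family,API,22.9
Lasioglossum leucopus,family,RAN,6.3
Lasioglossum leucopus,family,AST,2.5
Lasioglossum leucopus,family,other,0.3
Lasioglossum leucozonium,family,AST,95.3
Lasioglossum leucozonium,family,RAN,4.7
Lasioglossum malachurum,family,AST,73.1
Lasioglossum malachurum,family,BRA,9.9
Lasioglossum malachurum,family,ROS,3.3
Lasioglossum malachurum,family,other,13.7
Lasioglossum morio,family,BRA,51.2
Lasioglossum morio,family,AST,15.1
Lasioglossum morio,family,API,12.1
Lasioglossum morio,family,CAP,11.2
Lasioglossum morio,family,ROS,8.4
Lasioglossum morio,family,other,2.1
Lasioglossum parvulum,family,ROS,28.5
Lasioglossum parvulum,family,LAM,23.5
Lasioglossum parvulum,family,RAN,20.2
Lasioglossum parvulum,family,API,11.2
Lasioglossum parvulum,family,ACE,9.4
Lasioglossum parvulum,family,AST,5.9
Lasioglossum parvulum,family,other,1.3
Lasioglossum pauxillum,family,AST,62.1
Lasioglossum pauxillum,family,API,9.8
Lasioglossum pauxillum,family,RAN,9.4
Lasioglossum pauxillum,family,ROS,8.7
Lasioglossum pauxillum,family,BRA,3.5
Lasioglossum pauxillum,family,VER,2.3
Lasioglossum pauxillum,family,FAB,2.2
Lasioglossum pauxillum,family,other,2.0
Lasioglossum villosulum,family,AST,100.0
Lasioglossum xanthopus,family,AST,67.8
Lasioglossum xanthopus,family,BRA,32.0
Lasioglossum xanthopus,family,other,0.2
Lasioglossum zonulum,family,ROS,53.6
Lasioglossum zonulum,family,AST,21.6
Lasioglossum zonulum,family,CAR,12.9
Lasioglossum zonulum,family,RAN,6.1
Lasioglossum zonulum,family,CAP,4.3
Lasioglossum zonulum,family,other,1.4
Melitta tricincta,family,ORO,100.0
Melitta tricincta,genus,Odontites,100.0
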