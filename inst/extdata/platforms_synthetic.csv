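"id","lon","lat","basin"
"P001",-49.27299,-2.8,"Ceara"
"P002",-49.3,-2.77302,"Ceara"
"P003",-49.32701,-2.8,"Ceara"
"P004",-49.3,-2.82698,"Ceara"
"P005",-49.27298,-3.1,"Ceara"
"P006",-49.3,-3.07302,"Ceara"
"P007",-49.32702,-3.1,"Ceara"
"P008",-49.3,-3.12698,"Ceara"
"P009",-49.27294,-4.4,"Potiguar"
"P010",-49.29164,-4.37434,"Potiguar"
"P011",-49.32189,-4.38414,"Potiguar"
"P012",-49.32189,-4.41586,"Potiguar"
"P013",-49.29164,-4.42566,"Potiguar"
"P014",-49.27293,-4.8,"Potiguar"
"P015",-49.29163,-4.77434,"Potiguar"
"P016",-49.3219,-4.78414,"Potiguar"
"P017",-49.3219,-4.81586,"Potiguar"
"P018",-49.29163,-4.82566,"Potiguar"
"P019",-49.27259,-10.2,"Sergipe-Alagoas"
"P020",-49.3,-10.17302,"Sergipe-Alagoas"
"P021",-49.32741,-10.2,"Sergipe-Alagoas"
"P022",-49.3,-10.22698,"Sergipe-Alagoas"
"P023",-49.27252,-10.9,"Sergipe-Alagoas"
"P024",-49.3,-10.87302,"Sergipe-Alagoas"
"P025",-49.32748,-10.9,"Sergipe-Alagoas"
"P026",-49.3,-10.92698,"Sergipe-Alagoas"
"P027",-49.27246,-11.6,"Sergipe-Alagoas"
"P028",-49.3,-11.57302,"Sergipe-Alagoas"
"P029",-49.32754,-11.6,"Sergipe-Alagoas"
"P030",-49.3,-11.62698,"Sergipe-Alagoas"
"P031",-49.3,-13.5,"Camamu"
"P032",-48.77147,-19,"Espirito Santo"
"P033",-48.78573,-18.97663,"Espirito Santo"
"P034",-48.81427,-18.97663,"Espirito Santo"
"P035",-48.82853,-19,"Espirito Santo"
"P036",-48.81427,-19.02337,"Espirito Santo"
"P037",-48.78573,-19.02337,"Espirito Santo"
"P038",-48.77134,-19.7,"Espirito Santo"
"P039",-48.79114,-19.67434,"Espirito Santo"
"P040",-48.82318,-19.68414,"Espirito Santo"
"P041",-48.82318,-19.71586,"Espirito Santo"
"P042",-48.79114,-19.72566,"Espirito Santo"
"P043",-48.77122,-20.4,"Espirito Santo"
"P044",-48.7911,-20.37434,"Espirito Santo"
"P045",-48.82329,-20.38414,"Espirito Santo"
"P046",-48.82329,-20.41586,"Espirito Santo"
"P047",-48.7911,-20.42566,"Espirito Santo"
"P048",-48.37102,-21.4,"Campos"
"P049",-48.3778,-21.38266,"Campos"
"P050",-48.39497,-21.37343,"Campos"
"P051",-48.41449,-21.37663,"Campos"
"P052",-48.42723,-21.39077,"Campos"
"P053",-48.42723,-21.40923,"Campos"
"P054",-48.41449,-21.42337,"Campos"
"P055",-48.39497,-21.42657,"Campos"
"P056",-48.3778,-21.41734,"Campos"
"P057",-48.37096,-21.7,"Campos"
"P058",-48.37776,-21.68266,"Campos"
"P059",-48.39496,-21.67343,"Campos"
"P060",-48.41452,-21.67663,"Campos"
"P061",-48.42729,-21.69077,"Campos"
"P062",-48.42729,-21.70923,"Campos"
"P063",-48.41452,-21.72337,"Campos"
"P064",-48.39496,-21.72657,"Campos"
"P065",-48.37776,-21.71734,"Campos"
"P066",-48.3709,-22,"Campos"
"P067",-48.37771,-21.98266,"Campos"
"P068",-48.39495,-21.97343,"Campos"
"P069",-48.41455,-21.97663,"Campos"
"P070",-48.42734,-21.99077,"Campos"
"P071",-48.42734,-22.00923,"Campos"
"P072",-48.41455,-22.02337,"Campos"
"P073",-48.39495,-22.02657,"Campos"
"P074",-48.37771,-22.01734,"Campos"
"P075",-48.37084,-22.3,"Campos"
"P076",-48.37938,-22.28092,"Campos"
"P077",-48.4,-22.27302,"Campos"
"P078",-48.42062,-22.28092,"Campos"
"P079",-48.42916,-22.3,"Campos"
"P080",-48.42062,-22.31908,"Campos"
"P081",-48.4,-22.32698,"Campos"
"P082",-48.37938,-22.31908,"Campos"
"P083",-48.37078,-22.6,"Campos"
"P084",-48.37934,-22.58092,"Campos"
"P085",-48.4,-22.57302,"Campos"
"P086",-48.42066,-22.58092,"Campos"
"P087",-48.42922,-22.6,"Campos"
"P088",-48.42066,-22.61908,"Campos"
"P089",-48.4,-22.62698,"Campos"
"P090",-48.37934,-22.61908,"Campos"
"P091",-48.37071,-22.9,"Campos"
"P092",-48.37929,-22.88092,"Campos"
"P093",-48.4,-22.87302,"Campos"
"P094",-48.42071,-22.88092,"Campos"
"P095",-48.42929,-22.9,"Campos"
"P096",-48.42071,-22.91908,"Campos"
"P097",-48.4,-22.92698,"Campos"
"P098",-48.37929,-22.91908,"Campos"
"P099",-48.37065,-23.2,"Campos"
"P100",-48.37924,-23.18092,"Campos"
"P101",-48.4,-23.17302,"Campos"
"P102",-48.42076,-23.18092,"Campos"
"P103",-48.42935,-23.2,"Campos"
"P104",-48.42076,-23.21908,"Campos"
"P105",-48.4,-23.22698,"Campos"
"P106",-48.37924,-23.21908,"Campos"
"P107",-48.07051,-23.8,"Santos"
"P108",-48.1,-23.77302,"Santos"
"P109",-48.12949,-23.8,"Santos"
"P110",-48.1,-23.82698,"Santos"
"P111",-48.07042,-24.2,"Santos"
"P112",-48.1,-24.17302,"Santos"
"P113",-48.12958,-24.2,"Santos"
"P114",-48.1,-24.22698,"Santos"
"P115",-48.07033,-24.6,"Santos"
"P116",-48.1,-24.57302,"Santos"
"P117",-48.12967,-24.6,"Santos"
"P118",-48.1,-24.62698,"Santos"
"P119",-48.07023,-25,"Santos"
"P120",-48.1,-24.97302,"Santos"
"P121",-48.12977,-25,"Santos"
"P122",-48.1,-25.02698,"Santos"
"P123",-48.07013,-25.4,"Santos"
"P124",-48.1,-25.37302,"Santos"
"P125",-48.12987,-25.4,"Santos"
"P126",-48.1,-25.42698,"Santos"
"P127",-48.07003,-25.8,"Santos"
"P128",-48.1,-25.77302,"Santos"
"P129",-48.12997,-25.8,"Santos"
"P130",-48.1,-25.82698,"Santos"
"P131",-48.06993,-26.2,"Santos"
"P132",-48.11503,-26.17663,"Santos"
"P133",-48.11503,-26.22337,"Santos"
"P134",-48.06983,-26.6,"Santos"
"P135",-48.11509,-26.57663,"Santos"
"P136",-48.11509,-26.62337,"Santos"
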