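pigment,color_class,wavenumber,citation
uroporphyrin I,red,1335,"Williams et al. 2017 (reported as uroporphyrin I or III; the two are spectrally conflated)"
uroporphyrin I,red,1445,"Williams et al. 2017 (reported as uroporphyrin I or III; the two are spectrally conflated)"
uroporphyrin I,red,1556,"Williams et al. 2017 (reported as uroporphyrin I or III; the two are spectrally conflated)"
copper-uroporphyrin,red,1310,"Shelnutt 1981; Shelnutt 1982; Shelnutt et al. 1984"
copper-uroporphyrin,red,1379,"Shelnutt 1981; Shelnutt 1982; Shelnutt et al. 1984"
copper-uroporphyrin,red,1403,"Shelnutt 1981; Shelnutt 1982; Shelnutt et al. 1984"
copper-uroporphyrin,red,1499,"Shelnutt 1981; Shelnutt 1982; Shelnutt et al. 1984"
copper-uroporphyrin,red,1582,"Shelnutt 1981; Shelnutt 1982; Shelnutt et al. 1984"
copper-uroporphyrin,red,1637,"Shelnutt 1981; Shelnutt 1982; Shelnutt et al. 1984"
FeIII-uroporphyrin,red,1307,"Shelnutt 1982"
FeIII-uroporphyrin,red,1376,"Shelnutt 1982"
FeIII-uroporphyrin,red,1402,"Shelnutt 1982"
FeIII-uroporphyrin,red,1489,"Shelnutt 1982"
FeIII-uroporphyrin,red,1581,"Shelnutt 1982"
FeIII-uroporphyrin,red,1627,"Shelnutt 1982"
biliverdin,green,1252,"Margulies and Toporowicz 1984; Holt et al. 1989"
biliverdin,green,1273,"Margulies and Toporowicz 1984; Holt et al. 1989"
biliverdin,green,1606,"Margulies and Toporowicz 1984; Holt et al. 1989"
biliverdin,green,1608,"Margulies and Toporowicz 1984; Holt et al. 1989"
cobalamin,green,1495,"Puckett et al. 1996; Galluzzi et al. 1974"
cobalamin,green,1502,"Puckett et al. 1996; Galluzzi et al. 1974"
xanthine,yellow,862,"Muniz-Miranda et al. 2018"
xanthine,yellow,870,"Muniz-Miranda et al. 2018"
xanthine,yellow,1303,"Muniz-Miranda et al. 2018"
xanthine,yellow,1398,"Muniz-Miranda et al. 2018"
xanthine,yellow,1521,"Muniz-Miranda et al. 2018"
xanthine,yellow,1573,"Muniz-Miranda et al. 2018"
xanthine,yellow,1593,"Muniz-Miranda et al. 2018"
xanthine,yellow,1598,"Muniz-Miranda et al. 2018"
pheomelanin,yellow,507,"Galvan et al. 2013"
pheomelanin,yellow,1150,"Galvan et al. 2013"
pheomelanin,yellow,1488,"Galvan et al. 2013"
pheomelanin,yellow,1490,"Galvan et al. 2013"
bilirubin,yellow,692,"Dybas et al. 2018"
bilirubin,yellow,1294,"Dybas et al. 2018"
melanin,black,1109,"Centeno and Shamir 2008; Williams et al. 2016 (eumelanin)"
melanin,black,1360,"Centeno and Shamir 2008; Williams et al. 2016 (eumelanin)"
melanin,black,1400,"Centeno and Shamir 2008; Williams et al. 2016 (eumelanin)"
melanin,black,1590,"Centeno and Shamir 2008; Williams et al. 2016 (eumelanin)"
melanin,black,1600,"Centeno and Shamir 2008; Williams et al. 2016 (eumelanin)"
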