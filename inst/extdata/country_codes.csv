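name,iso3
Algeria,DZA
Angola,AGO
Benin,BEN
Botswana,BWA
Burkina Faso,BFA
Burundi,BDI
Cabo Verde,CPV
Cape Verde,CPV
Cameroon,CMR
Central African Republic,CAF
Chad,TCD
Comoros,COM
Congo,COG
Republic of the Congo,COG
Republic of Congo,COG
Congo-Brazzaville,COG
Democratic Republic of the Congo,COD
DR Congo,COD
Congo-Kinshasa,COD
Zaire,COD
Cote d'Ivoire,CIV
Ivory Coast,CIV
Djibouti,DJI
Egypt,EGY
Equatorial Guinea,GNQ
Eritrea,ERI
Eswatini,SWZ
Swaziland,SWZ
Ethiopia,ETH
Gabon,GAB
Gambia,GMB
Ghana,GHA
Guinea,GIN
Guinea-Bissau,GNB
Kenya,KEN
Lesotho,LSO
Liberia,LBR
Libya,LBY
Madagascar,MDG
Malawi,MWI
Mali,MLI
Mauritania,MRT
Mauritius,MUS
Morocco,MAR
Mozambique,MOZ
Namibia,NAM
Niger,NER
Nigeria,NGA
Rwanda,RWA
Sao Tome and Principe,STP
Senegal,SEN
Seychelles,SYC
Sierra Leone,SLE
Somalia,SOM
South Africa,ZAF
South Sudan,SSD
Sudan,SDN
Tanzania,TZA
United Republic of Tanzania,TZA
Togo,TGO
Tunisia,TUN
Uganda,UGA
Zambia,ZMB
Zimbabwe,ZWE
France,FRA
United Kingdom,GBR
Belgium,BEL
Netherlands,NLD
Portugal,PRT
United States,USA
United States of America,USA
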