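surface_form,iso2
India,IN
Indian,IN
Indians,IN
United States,US
United States of America,US
America,US
American,US
Americans,US
United Kingdom,GB
Britain,GB
British,GB
South Africa,ZA
South African,ZA
South Africans,ZA
Nigeria,NG
Nigerian,NG
Nigerians,NG
Kenya,KE
Kenyan,KE
Kenyans,KE
Brazil,BR
Brazilian,BR
Brazilians,BR
France,FR
French,FR
Germany,DE
German,DE
Germans,DE
Italy,IT
Italian,IT
Italians,IT
Spain,ES
Spanish,ES
Spaniards,ES
Australia,AU
Australian,AU
Australians,AU
Canada,CA
Canadian,CA
Canadians,CA
Japan,JP
Japanese,JP
Philippines,PH
Filipino,PH
Filipinos,PH
Mexico,MX
Mexican,MX
Mexicans,MX
Egypt,EG
Egyptian,EG
Egyptians,EG
Poland,PL
Polish,PL
Poles,PL
Sweden,SE
Swedish,SE
Swedes,SE
Thailand,TH
Thai,TH
Thais,TH
China,CN
Chinese,CN
Argentina,AR
Argentine,AR
Argentinian,AR
Chile,CL
Chilean,CL
Peru,PE
Peruvian,PE
Colombia,CO
Colombian,CO
Ghana,GH
Ghanaian,GH
Ethiopia,ET
Ethiopian,ET
Uganda,UG
Ugandan,UG
Tanzania,TZ
Tanzanian,TZ
Zimbabwe,ZW
Zimbabwean,ZW
Sudan,SD
Sudanese,SD
South Sudan,SS
South Sudanese,SS
Guinea,GN
Guinean,GN
Papua New Guinea,PG
Equatorial Guinea,GQ
New Zealand,NZ
Zealanders,NZ
Ireland,IE
Irish,IE
Netherlands,NL
Dutch,NL
Belgium,BE
Belgian,BE
Portugal,PT
Portuguese,PT
Greece,GR
Greek,GR
Turkey,TR
Turkish,TR
Russia,RU
Russian,RU
Russians,RU
Ukraine,UA
Ukrainian,UA
Ukrainians,UA
Pakistan,PK
Pakistani,PK
Pakistanis,PK
Bangladesh,BD
Bangladeshi,BD
Bangladeshis,BD
Nepal,NP
Nepali,NP
Sri Lanka,LK
Sri Lankan,LK
Indonesia,ID
Indonesian,ID
Indonesians,ID
Malaysia,MY
Malaysian,MY
Malaysians,MY
Vietnam,VN
Vietnamese,VN
Singapore,SG
Singaporean,SG
Singaporeans,SG
South Korea,KR
South Korean,KR
South Koreans,KR
Israel,IL
Israeli,IL
Israelis,IL
Saudi Arabia,SA
Saudi,SA
Saudis,SA
Iran,IR
Iranian,IR
Iranians,IR
Iraq,IQ
Iraqi,IQ
Iraqis,IQ
Morocco,MA
Moroccan,MA
Moroccans,MA
Norway,NO
Norwegian,NO
Norwegians,NO
Denmark,DK
Danish,DK
Danes,DK
Finland,FI
Finnish,FI
Finns,FI
Austria,AT
Austrian,AT
Austrians,AT
Switzerland,CH
Swiss,CH
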