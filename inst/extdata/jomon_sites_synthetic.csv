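"site","diet_group","n","latitude","longitude"
"Funadomari","HOK",5,45.42,141.04
"Takasago","HOK",4,42.55,140.77
"Irie","HOK",2,42.57,140.74
"Kotan Onsen","HOK",4,42.75,140.42
"Kitakogane","HOK",4,42.46,140.91
"Miyano","NEH",3,38.93,141.6
"Ebishima","NEH",17,38.55,141.3
"Wakaumi","CCH",1,35.65,140.05
"Yoshigo","CCH",11,34.65,137.4
"Ikawazu","CCH",4,34.63,137.18
"Tochibara","ICH",3,36.1,138.3
"Tsukumo","SWJ",20,34.5,133.6
"Yamaga","SWJ",4,33.02,130.5
"Einomaru","SWJ",1,33.08,130.46
"Todoroki","SWJ",1,32.02,130.7
"Goryo","SWJ",1,32.08,130.62
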