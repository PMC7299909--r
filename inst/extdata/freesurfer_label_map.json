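{
  "lateral_ventricle": [4, 43],
  "inferior_temporal": [1009, 2009],
  "middle_temporal": [1015, 2015],
  "superior_temporal": [1030, 2030],
  "temporal_pole": [1033, 2033],
  "transverse_temporal": [1034, 2034],
  "bankssts": [1001, 2001],
  "fusiform": [1007, 2007],
  "entorhinal": [1006, 2006],
  "parahippocampal": [1016, 2016],
  "frontal": [1003, 1012, 1014, 1017, 1018, 1019, 1020, 1024, 1027, 1028, 1032,
              2003, 2012, 2014, 2017, 2018, 2019, 2020, 2024, 2027, 2028, 2032],
  "parietal": [1008, 1022, 1029, 1031, 2008, 2022, 2029, 2031],
  "precuneus_pcc": [1010, 1023, 1025, 2010, 2023, 2025],
  "lateral_temporal": [1001, 1009, 1015, 1030, 1034,
                       2001, 2009, 2015, 2030, 2034],
  "caudate": [11, 50],
  "putamen": [12, 51],
  "cerebellum": [7, 8, 46, 47],
  "cerebral_white_matter": [2, 41],
  "grey_matter": [3, 42]
}
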