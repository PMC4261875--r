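clade	age
african_green_monkey;aye_aye;cat;chimpanzee;cow;galago;golden_mole;gorilla;horse;horseshoe_bat;human;macaque;marmoset;orangutan;sloth;spider_monkey;squirrel_monkey	105
african_green_monkey;aye_aye;cat;chimpanzee;cow;galago;gorilla;horse;horseshoe_bat;human;macaque;marmoset;orangutan;sloth;spider_monkey;squirrel_monkey	101.1
african_green_monkey;aye_aye;cat;chimpanzee;cow;galago;gorilla;horse;horseshoe_bat;human;macaque;marmoset;orangutan;spider_monkey;squirrel_monkey	96
cat;cow;horse;horseshoe_bat	81
cat;cow;horse	78
cow;horse	76
african_green_monkey;aye_aye;chimpanzee;galago;gorilla;human;macaque;marmoset;orangutan;spider_monkey;squirrel_monkey	74
aye_aye;galago	60
african_green_monkey;chimpanzee;gorilla;human;macaque;marmoset;orangutan;spider_monkey;squirrel_monkey	43
african_green_monkey;chimpanzee;gorilla;human;macaque;orangutan	29
chimpanzee;gorilla;human;orangutan	16
chimpanzee;gorilla;human	9
chimpanzee;human	6.5
african_green_monkey;macaque	14
marmoset;spider_monkey;squirrel_monkey	24
marmoset;squirrel_monkey	20
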