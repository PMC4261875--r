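(golden_mole:105,(sloth:101.1,((horseshoe_bat:81,(cat:78,(horse:76,cow:76):2):3):15,((aye_aye:60,galago:60):14,(((orangutan:16,(gorilla:9,(human:6.5,chimpanzee:6.5):2.5):7):13,(macaque:14,african_green_monkey:14):15):14,(spider_monkey:24,(squirrel_monkey:20,marmoset:20):4):19):31):22):5):3.9);
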