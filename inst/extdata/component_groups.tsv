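component	group
Africa A	Africa
Africa B	Africa
Central Europe	Europe
South Europe	Europe
Western Europe	Europe
Scandinavia	Europe
East Asia	East Asia
Far East Asia	East Asia
Southeast Asia	East Asia
Central Asia	Central Asia
India	Central Asia
Native America	America
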