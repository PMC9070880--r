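801e1e3554bb16b5fc9c69e352052389 network.csv
3a5634972e4c0ace454661031ad67d64 districts.csv
952c7db90d01e3f411a472d062297d6a endowments.csv
f0cfb2d10e14db7522e89a17e6ccabe2 cities.csv
7935d422a216be0c58fe3d408ff7e049 config.json
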