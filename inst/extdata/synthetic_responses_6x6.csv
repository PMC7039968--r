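individual,chx_0.1,oct_0.1,hex_0.1,chx_10,oct_10,hex_10
locust1,7.6,15.1,11.4,19.2,27.3,22.6
locust2,8.9,13.2,10.1,21.0,25.4,24.1
locust3,6.2,14.8,12.3,18.4,26.9,21.2
locust4,9.1,12.9,9.6,20.3,24.8,23.5
locust5,7.0,15.6,11.9,19.8,27.9,22.0
locust6,8.3,13.7,10.7,20.9,26.1,23.9
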