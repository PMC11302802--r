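{"kind":"detectability","anchors":[{"score":1,"probability":0.0001},{"score":2,"probability":0.002},{"score":3,"probability":0.005},{"score":4,"probability":0.01},{"score":5,"probability":0.02},{"score":6,"probability":0.05},{"score":7,"probability":0.1},{"score":8,"probability":0.15},{"score":9,"probability":0.2},{"score":10,"probability":0.3}]}
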