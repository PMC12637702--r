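{"attractors":["000","111"],"basinSizes":[5,3],"basinCoherence":[0.666666666666667,0.444444444444444],"attractorCoherence":[1,0.666666666666667],"networkCoherence":0.583333333333333}
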