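{"system":{"masses":[1,1],"positions":[[-0.6,0,0],[0.6,0,0]],"velocities":[[0,0,0],[0,0,0]],"bonds":[{"i":1,"j":2,"k":1,"r0":1}]},"params":{"dt":0.001,"nsteps":10000,"friction_gamma":0,"output_interval":10,"seed":0}}
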