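synapse	synaptic signalling genes	G00001	G00002	G00003	G00004
axon	axonogenesis genes	G00005	G00006	G00007
transport	ion transport genes	G00008	G00009	G00010	G00011	G00012
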