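{"h2_0.741":{"basis":"STO-3G","e_hf":-1.11670613723612,"e_fci":-1.13727440552946,"n_terms":14},"h_chain_6":{"basis":"STO-3G","n_terms_local_3e8":1814}}
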