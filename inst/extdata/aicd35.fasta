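>AICD35 synthetic reconstruction | 35-residue APP intracellular domain fragment with an N-terminal Gly-Ala-Met expression scar; YENPTY at 22-27; net charge -2e with charged termini and neutral His
GAMDAAVTPEERHLSKMQQNGYENPTYKFFEQMQN
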