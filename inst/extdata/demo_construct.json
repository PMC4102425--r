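{"cut_sites":[{"position":220,"overhang_length":4,"orientation":"forward"},{"position":280,"overhang_length":4,"orientation":"reverse"}],"excised_interval":[221,280],"primer_fwd":"ATCCCCCAATTATGTGGCAT","primer_rev":"CTTGGCCTGGAGAATCTACG"}
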