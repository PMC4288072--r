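possibly
presumed
suspected
could
may
unlikely
probable
likely
questionable
##terminators
but
however
although
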