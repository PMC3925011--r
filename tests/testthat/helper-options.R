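## run every block to the end even when several numeric comparisons fail
options(testthat.progress.max_fails = Inf)
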