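# Keep the runner going through every file even when scenario-level checks
# fail, so the whole suite is always reported.
options(testthat.progress.max_fails = 200L)
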