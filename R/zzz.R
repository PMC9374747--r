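.onLoad <- function(libname, pkgname) {
  register_count_method("log_welch", function(a, b) {
    welch_test(log2(a + 1), log2(b + 1))$p
  })
}
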