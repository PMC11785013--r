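# Shared toy fixtures, built once per test run.
toy_cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(toy_cache$fix)) {
    native <- make_toy_two_domain_system(toy_spec(seed = 1L))
    wt <- make_disordered_tail(native)
    ff_plain <- build_forcefield(wt$structure)
    ff_masked <- apply_disorder_mask(ff_plain, wt$disorder)
    meta <- attr(native, "toy")
    toy_cache$fix <- list(native = native, with_tail = wt$structure,
                          disorder = wt$disorder, ff = ff_plain,
                          ff_masked = ff_masked, meta = meta)
  }
  toy_cache$fix
}
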