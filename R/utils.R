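# name-based list override with replacement (not recursive-merge)
# semantics: nested lists such as cap/lesion specs are replaced whole
override_list <- function(defaults, overrides) {
  stopifnot(is.list(defaults), is.list(overrides))
  if (length(overrides) > 0 &&
    (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("overrides must be named", call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  defaults
}
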