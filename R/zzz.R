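.onLoad <- function(libname, pkgname) {
  if (!length(ls(.dialect_registry))) init_dialect_registry()
  if (!length(ls(.ee_equations))) init_ee_registry()
  invisible()
}
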