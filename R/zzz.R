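# Register the built-in operations so serialized graphs can be rebuilt.
.onLoad <- function(libname, pkgname) {
  for (spec in list(const_spec(), join_spec(k_any()), logical_not_spec(),
                    ensemble_state_spec(), noop_spec(), read_input_spec(),
                    modify_input_spec(), mdrun_spec())) {
    register_operation(spec, overwrite = TRUE)
  }
  invisible()
}
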