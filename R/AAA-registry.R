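# Operation registry shared by replay() and the pipeline runner.
# Defined first so every module file can register its operations at
# load time.  Handlers take (ds, parameters, resources) and return the
# updated dataset.

op_registry <- new.env(parent = emptyenv())

register_operation <- function(name, handler) {
  assign(name, handler, envir = op_registry)
  invisible(name)
}

#' Names of operations that can be replayed from a process record
#' @return character vector of registered operation names.
#' @export
registered_operations <- function() {
  sort(ls(op_registry))
}
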