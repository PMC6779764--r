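#' @include AllClasses.R
NULL

## rbind a list of data.frames, ignoring NULLs; NULL when nothing remains
.rbindRows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
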