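# shared internal helpers

# extract the numeric matrix from a ContactMap, NormalizedMap, any list
# carrying a $values matrix, or a bare matrix
.map_values <- function(H) {
  if (is.list(H) && !is.null(H$values)) return(as.matrix(H$values))
  as.matrix(H)
}
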