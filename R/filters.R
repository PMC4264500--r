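# Matrix filtering front-ends for the compiled IIR core.  Semantics match
# signal::filter / signal::filtfilt applied columnwise (filtfilt zero-pads
# by twice the filter length before the backward pass), but one call
# filters all trials x channels of a band at once.

filter_mat <- function(filt, X, causal = TRUE) {
  if (causal) return(iir_filter_mat(filt$b, filt$a, X))
  n <- nrow(X)
  pad <- matrix(0, 2 * max(length(filt$a), length(filt$b)), ncol(X))
  Y <- iir_filter_mat(filt$b, filt$a, rbind(X, pad))
  Y <- iir_filter_mat(filt$b, filt$a, Y[nrow(Y):1, , drop = FALSE])
  Y[seq(nrow(Y), nrow(Y) - n + 1L), , drop = FALSE]
}
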