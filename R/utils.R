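`%||%` <- function(a, b) if (is.null(a)) b else a

# Root-mean-square with configurable divisor ("n" RMSE convention or "n-1").
.rms <- function(x, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  n <- length(x)
  sqrt(sum(x^2) / if (divisor == "n") n else (n - 1L))
}
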