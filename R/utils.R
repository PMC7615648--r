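# internal helpers shared across modules

# reverse complement of character DNA strings (A/C/G/T/N)
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

# %.17g formatting: doubles survive a write/read round trip exactly
.num17 <- function(x) sprintf("%.17g", x)

# fixed-precision formatting for report tables (deterministic output files)
.num10 <- function(x) sprintf("%.10g", x)
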