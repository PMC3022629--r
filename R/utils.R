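# numeric formatting shared by the writers

# result-table precision: 6 significant digits, "NA" literal for missing
format_num <- function(x, scientific = FALSE) {
  out <- if (scientific) {
    formatC(x, digits = 5, format = "e")
  } else {
    vapply(x, function(v) formatC(signif(v, 6), digits = 6, format = "g"),
           character(1L))
  }
  out[!is.finite(x) & !is.na(x)] <- as.character(x[!is.finite(x) & !is.na(x)])
  out[is.na(x)] <- "NA"
  trimws(out)
}

# full double precision, for fixtures that must round-trip exactly
format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
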