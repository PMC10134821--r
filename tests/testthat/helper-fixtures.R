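# Shared fixtures built in code.

# Tiny exact-line kinetic table written to a temp CSV.
write_tiny_table <- function(times = c(0, 0.25, 0.5),
                             wells = c(A1 = 0.1, A2 = 0.2),
                             path = tempfile(fileext = ".csv")) {
  df <- data.frame(time = times)
  for (w in names(wells)) df[[w]] <- rep(wells[[w]], length(times))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Standards exactly on OD = slope * C + intercept.
exact_standards <- function(conc = c(0, 0.05, 0.1, 0.2, 0.4),
                            slope = 1, intercept = 0.05) {
  data.frame(concentration = conc, od = intercept + slope * conc)
}

# 72-h / 15-min plate-reader schedule (289 points).
dye_times <- function() seq(0, 72, by = 0.25)
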