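# Write a small per-child survey CSV and return its path.
write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

tiny_survey_df <- function() {
  data.frame(age = c(10.2, 24, 36.5),
             haz = c(-1.2, -2.5, 0.3),
             whz = c(0.1, -0.5, -1.4),
             waz = c(-0.7, -1.1, -2.2),
             wt = c(1.0, 1.5, 0.5))
}
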