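## Cross-implementation oracle hook (testing aid): exports a discretized
## ROI to CSV and runs the bundled Python oracle, which recomputes the 93
## intensity/texture features from their standard definitions with an
## independent implementation (numpy/scipy).  Returns the named feature
## vector, or NULL when no python interpreter is available.
oracle_texture_features <- function(vol, mask, n_bins = 32) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") return(NULL)
  script <- system.file("oracle", "radiomics_oracle.py",
                        package = "pitradiomics")
  stop_if_not(nzchar(script), "bundled oracle script not found")
  voln <- normalize_roi(vol, mask)
  d <- discretize(voln, mask, n_bins)
  lin <- which(mask$data)
  idx <- arrayInd(lin, dim(mask$data))
  tab <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                    value = voln$data[lin], level = d$levels[lin])
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.csv(tab, fin, row.names = FALSE)
  dm <- dim(mask$data)
  status <- system2(py, c(script, fin, fout, dm[1], dm[2], dm[3], n_bins,
                          mask$spacing[1], mask$spacing[2], mask$spacing[3]),
                    stdout = FALSE, stderr = "")
  stop_if_not(status == 0, "python oracle exited with status %d", status)
  res <- utils::read.csv(fout, stringsAsFactors = FALSE)
  stats::setNames(res$value, res$name)
}
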