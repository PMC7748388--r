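# synthetic identity model: baseline = css * crcl, so expected doses are
# forced by construction and independent of the packaged coefficient table
identity_model <- function(max_daily_cba = 300) {
  dosing_model("identity",
               data.frame(crcl_upper = c(0, 1000),
                          cba_per_css = c(0, 1000)),
               interpolate = TRUE, max_daily_cba = max_daily_cba)
}

cli_script <- function() {
  system.file("cli", "colidose.R", package = "colidose", mustWork = TRUE)
}

# run the CLI in a child Rscript that sees the same library paths
run_cli <- function(...) {
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"),
    c(cli_script(), c(...)),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = ":")))
  ))
  list(status = attr(out, "status") %||% 0L,
       text = paste(out, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
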