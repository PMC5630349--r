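# Shared test fixtures and utilities.

# Fresh scratch directory under the session tempdir (removed with it).
withr_local_tempdir <- function() {
  d <- tempfile("studydir")
  dir.create(d)
  d
}
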