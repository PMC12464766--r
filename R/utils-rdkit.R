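# Interface to the batched RDKit helper (inst/python/chemio.py).
#
# One python subprocess per *batch* of molecules; requests and responses are
# JSON on stdin/stdout. Conformer embedding (ETKDG) takes an explicit random
# seed, so parsing is bit-deterministic.

.pythonBin <- function() {
  for (cand in c("python", "python3")) {
    bin <- Sys.which(cand)
    if (nzchar(bin)) return(bin)
  }
  stop("no 'python' interpreter found on PATH; the RDKit helper requires one",
       call. = FALSE)
}

.chemioScript <- function() {
  p <- system.file("python", "chemio.py", package = "ADquadrant")
  if (!nzchar(p)) p <- file.path("inst", "python", "chemio.py")  # source tree
  if (!file.exists(p)) stop("chemio.py helper script not found", call. = FALSE)
  p
}

.chemio <- function(req) {
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA)
  errfile <- tempfile(fileext = ".err")
  on.exit(unlink(errfile), add = TRUE)
  out <- suppressWarnings(system2(.pythonBin(), shQuote(.chemioScript()),
                                  stdin = infile, stdout = TRUE,
                                  stderr = errfile))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RDKit helper failed: ",
         paste(readLines(errfile, warn = FALSE), collapse = " "),
         call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)$result
}

.rdParseSmiles <- function(smiles, seed = 7L) {
  .chemio(list(op = "parse_smiles", smiles = as.list(smiles),
               seed = as.integer(seed)))
}

.rdParseSdf <- function(sdf_lines) {
  .chemio(list(op = "parse_sdf", sdf = paste(sdf_lines, collapse = "\n")))
}

# canonical isomeric SMILES of 3-D molblocks, stereo perceived from geometry
.rdCanonFromSdf <- function(sdf_lines) {
  res <- .chemio(list(op = "canon_from_sdf",
                      sdf = paste(sdf_lines, collapse = "\n")))
  vapply(res, function(x) {
    if (!is.null(x$error)) NA_character_ else x$canonical
  }, character(1))
}
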