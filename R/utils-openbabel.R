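#' @importFrom utils head tail read.csv write.csv
NULL

# Optional OpenBabel interface: used only for the extra empirical charge
# backends (eem, mmff94, qeq, eqeq). All structure perception and conformer
# embedding goes through the RDKit helper (see utils-rdkit.R), which is
# seed-deterministic; the OpenBabel charge models are deterministic given a
# fixed geometry, which is how they are invoked here.

.obabelBin <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("OpenBabel ('obabel') was not found on PATH; it is required only ",
         "for the eem/mmff94/qeq/eqeq charge backends.", call. = FALSE)
  }
  bin
}

.obabelRun <- function(args, stdin_text = NULL) {
  bin <- .obabelBin()
  infile <- NULL
  if (!is.null(stdin_text)) {
    infile <- tempfile(fileext = ".obin")
    writeLines(stdin_text, infile)
    on.exit(unlink(infile), add = TRUE)
  }
  errfile <- tempfile(fileext = ".err")
  on.exit(unlink(errfile), add = TRUE)
  out <- suppressWarnings(system2(bin, args = args,
                                  stdin = if (is.null(infile)) "" else infile,
                                  stdout = TRUE, stderr = errfile))
  status <- attr(out, "status")
  err <- tryCatch(readLines(errfile, warn = FALSE), error = function(e) character())
  list(stdout = as.character(out), stderr = err,
       status = if (is.null(status)) 0L else status)
}

# SDF text -> mol2 text with recomputed partial charges.
.obSdfToMol2 <- function(sdf_lines, charge_model) {
  res <- .obabelRun(c("-isdf", "-omol2", "--partialcharge", charge_model),
                    stdin_text = sdf_lines)
  if (length(res$stdout) == 0L) {
    stop("OpenBabel produced no mol2 output: ",
         paste(res$stderr, collapse = " "), call. = FALSE)
  }
  res$stdout
}

# Split multi-record mol2 text into per-record chunks.
.splitMol2Records <- function(mol2_lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", mol2_lines)
  if (length(starts) == 0L) return(list())
  ends <- c(tail(starts, -1L) - 1L, length(mol2_lines))
  Map(function(s, e) mol2_lines[s:e], starts, ends)
}

# Parse the ATOM section of one mol2 record.
.parseMol2Atoms <- function(rec) {
  a0 <- grep("^@<TRIPOS>ATOM", rec)
  stopifnot(length(a0) == 1L)
  a1 <- grep("^@<TRIPOS>", rec)
  a1 <- a1[a1 > a0]
  end <- if (length(a1)) a1[1] - 1L else length(rec)
  lines <- rec[(a0 + 1L):end]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  types <- vapply(fields, `[`, character(1), 6)
  data.frame(
    element = sub("\\..*$", "", types),
    x = as.numeric(vapply(fields, `[`, character(1), 3)),
    y = as.numeric(vapply(fields, `[`, character(1), 4)),
    z = as.numeric(vapply(fields, `[`, character(1), 5)),
    charge = as.numeric(vapply(fields, `[`, character(1), 9)),
    aromatic = grepl("\\.ar$", types),
    stringsAsFactors = FALSE
  )
}

# Minimal V2000 writer used to hand constructed geometry (conformers,
# syn-addition diols, mirrored copies) to external tools.
.sdfText <- function(elements, coords, bonds, title = "ADquadrant") {
  n <- length(elements)
  stopifnot(nrow(coords) == n)
  counts <- sprintf("%3d%3d  0  0  1  0  0  0  0  0999 V2000", n, nrow(bonds))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], elements)
  bl <- sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j, bonds$order)
  c(title, " ADquadrant", "", counts, atoms, bl, "M  END", "$$$$")
}
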