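#' Curated force-field validation test set
#'
#' The package ships a manifest of 52 high-resolution protein structures used
#' to benchmark force-field parameter sets: 39 solved by X-ray diffraction and
#' 13 by NMR, covering proteins of 17 to 326 residues. Nine proteins appear
#' twice, once per experimental method, and carry cross-references in
#' `paired_id`. Structures are covered either by all four GROMOS parameter
#' sets (45A4, 53A6, 54A7, 54A8) or by 54A7/54A8 only (`ff_coverage`).
#'
#' @param path Path to a tab-separated manifest. Defaults to the packaged
#'   test-set file. An en dash (`\enc{–}{-}`) or empty cell denotes an absent
#'   value.
#' @return A `data.frame` of class `ff_manifest`, one row per structure, with
#'   columns `pdb_id`, `protein_name`, `organism`, `n_residues`, `method`
#'   (`"xray"` or `"nmr"`), secondary-structure percentages `pct_310`,
#'   `pct_alpha`, `pct_beta` (beta = strand + bridge), `ph`, `resolution_A`,
#'   `r_work`, `r_free`, `ff_coverage` (`"all"` or `"54A7/8"`), `paired_id`,
#'   `nmr_data` (subsets of NOE/Jval/RDC, `+`-separated) and `note`.
#' @examples
#' m <- load_manifest()
#' nrow(m)                      # 52
#' table(m$method)              # 39 xray, 13 nmr
#' m[m$pdb_id == "1UBI", c("protein_name", "n_residues", "ff_coverage")]
#' @export
load_manifest <- function(path = system.file("extdata", "manifest.tsv",
                                             package = "ffval")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("manifest file not found: '", path, "'")
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character(), quote = "")
  if (nrow(raw) == 0L) {
    empty <- empty_manifest()
    return(empty)
  }
  required <- c("pdb_id", "protein_name", "organism", "n_residues", "method",
                "pct_310", "pct_alpha", "pct_beta", "ph", "resolution_A",
                "r_work", "r_free", "ff_coverage", "paired_id", "nmr_data",
                "note")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }

  absent <- function(x) !nzchar(x) | x == "–" | x == "-"
  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    out[absent(x)] <- NA_real_
    bad <- which(!absent(x) & is.na(out))
    if (length(bad)) {
      stop("manifest row ", bad[1L], " (", raw$pdb_id[bad[1L]],
           "): cannot parse '", x[bad[1L]], "' in column '", col, "'")
    }
    out
  }
  chr <- function(x) ifelse(absent(x), NA_character_, x)

  m <- data.frame(
    pdb_id       = raw$pdb_id,
    protein_name = raw$protein_name,
    organism     = raw$organism,
    n_residues   = as.integer(num(raw$n_residues, "n_residues")),
    method       = raw$method,
    pct_310      = num(raw$pct_310, "pct_310"),
    pct_alpha    = num(raw$pct_alpha, "pct_alpha"),
    pct_beta     = num(raw$pct_beta, "pct_beta"),
    ph           = num(raw$ph, "ph"),
    resolution_A = num(raw$resolution_A, "resolution_A"),
    r_work       = num(raw$r_work, "r_work"),
    r_free       = num(raw$r_free, "r_free"),
    ff_coverage  = raw$ff_coverage,
    paired_id    = chr(raw$paired_id),
    nmr_data     = chr(raw$nmr_data),
    note         = chr(raw$note),
    stringsAsFactors = FALSE
  )

  bad_id <- which(!grepl("^[0-9][A-Za-z0-9]{3}$", m$pdb_id))
  if (length(bad_id)) {
    stop("manifest row ", bad_id[1L], ": '", m$pdb_id[bad_id[1L]],
         "' is not a 4-character PDB accession")
  }
  dup <- m$pdb_id[duplicated(m$pdb_id)]
  if (length(dup)) stop("duplicate pdb_id in manifest: ", paste(dup, collapse = ", "))
  bad_m <- which(!m$method %in% c("xray", "nmr"))
  if (length(bad_m)) {
    stop("manifest row ", bad_m[1L], " (", m$pdb_id[bad_m[1L]],
         "): method must be 'xray' or 'nmr', got '", m$method[bad_m[1L]], "'")
  }
  bad_ff <- which(!m$ff_coverage %in% c("all", "54A7/8"))
  if (length(bad_ff)) {
    stop("manifest row ", bad_ff[1L], " (", m$pdb_id[bad_ff[1L]],
         "): ff_coverage must be 'all' or '54A7/8'")
  }
  if (any(m$method == "nmr" & !is.na(m$resolution_A))) {
    stop("NMR entries must not carry a crystallographic resolution")
  }
  if (any(m$method == "xray" & is.na(m$resolution_A))) {
    stop("X-ray entries must carry a resolution")
  }
  bad_n <- which(is.na(m$n_residues) | m$n_residues <= 0L)
  if (length(bad_n)) {
    stop("manifest row ", bad_n[1L], " (", m$pdb_id[bad_n[1L]],
         "): n_residues must be a positive integer")
  }
  # paired entries must resolve reciprocally and to the other method
  paired <- which(!is.na(m$paired_id))
  for (i in paired) {
    j <- match(m$paired_id[i], m$pdb_id)
    if (is.na(j)) {
      stop("entry ", m$pdb_id[i], " pairs to unknown accession ", m$paired_id[i])
    }
    if (m$method[j] == m$method[i]) {
      stop("entry ", m$pdb_id[i], " and its pair ", m$pdb_id[j],
           " were solved by the same method")
    }
    if (is.na(m$paired_id[j]) || m$paired_id[j] != m$pdb_id[i]) {
      stop("pairing of ", m$pdb_id[i], " is not reciprocal")
    }
  }
  class(m) <- c("ff_manifest", "data.frame")
  m
}

empty_manifest <- function() {
  m <- data.frame(
    pdb_id = character(), protein_name = character(), organism = character(),
    n_residues = integer(), method = character(), pct_310 = numeric(),
    pct_alpha = numeric(), pct_beta = numeric(), ph = numeric(),
    resolution_A = numeric(), r_work = numeric(), r_free = numeric(),
    ff_coverage = character(), paired_id = character(), nmr_data = character(),
    note = character(), stringsAsFactors = FALSE
  )
  class(m) <- c("ff_manifest", "data.frame")
  m
}

#' Study-design bookkeeping for a manifest
#'
#' Computes the sample size per parameter set and the total simulated time
#' implied by running every covered (structure, parameter set) combination
#' `replicates` times for `run_length_ns` nanoseconds. Structures with
#' `ff_coverage == "all"` contribute to all four parameter sets; structures
#' with `"54A7/8"` only to 54A7 and 54A8. With the packaged manifest, three
#' replicates of 15 ns give sample sizes of 120 (45A4, 53A6) and 156
#' (54A7, 54A8) and a total of 8.28 us of simulation.
#'
#' @param entries An `ff_manifest` (see [load_manifest()]).
#' @param replicates Number of replicate simulations per combination (>= 1).
#' @param run_length_ns Length of one production run in nanoseconds (> 0).
#' @return A list of class `ff_design_summary`: `n_structures`, `n_xray`,
#'   `n_nmr`, `n_distinct_proteins` (paired X-ray/NMR entries deduplicated),
#'   `residue_range`, `sample_size_per_ff` (named integer vector) and
#'   `total_sim_time_us`.
#' @examples
#' design_summary(load_manifest(), replicates = 3, run_length_ns = 15)
#' @export
design_summary <- function(entries, replicates = 3L, run_length_ns = 15) {
  stopifnot(is.data.frame(entries))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  if (!is.numeric(run_length_ns) || run_length_ns <= 0) {
    stop("run_length_ns must be > 0")
  }
  sets <- parameter_set_order()
  covered <- function(cov) if (identical(cov, "all")) sets else c("54A7", "54A8")
  n_cov <- vapply(sets, function(s) {
    sum(vapply(entries$ff_coverage, function(cov) s %in% covered(cov), logical(1)))
  }, numeric(1))
  sample_size <- as.integer(n_cov * replicates)
  names(sample_size) <- sets
  total_ns <- sum(n_cov) * replicates * run_length_ns

  n_pairs <- if (nrow(entries)) sum(!is.na(entries$paired_id)) %/% 2L else 0L
  out <- list(
    n_structures        = nrow(entries),
    n_xray              = sum(entries$method == "xray"),
    n_nmr               = sum(entries$method == "nmr"),
    n_distinct_proteins = nrow(entries) - n_pairs,
    residue_range       = if (nrow(entries)) range(entries$n_residues) else c(NA_integer_, NA_integer_),
    sample_size_per_ff  = sample_size,
    total_sim_time_us   = total_ns / 1000
  )
  class(out) <- "ff_design_summary"
  out
}

#' @export
print.ff_design_summary <- function(x, ...) {
  cat("Force-field validation study design\n")
  cat(sprintf("  structures:        %d (%d X-ray, %d NMR; %d distinct proteins)\n",
              x$n_structures, x$n_xray, x$n_nmr, x$n_distinct_proteins))
  if (!is.na(x$residue_range[1])) {
    cat(sprintf("  residue range:     %d-%d\n", x$residue_range[1], x$residue_range[2]))
  }
  cat("  sample size per parameter set:\n")
  for (s in names(x$sample_size_per_ff)) {
    cat(sprintf("    %-5s %d\n", s, x$sample_size_per_ff[[s]]))
  }
  cat(sprintf("  total simulated time: %.2f us\n", x$total_sim_time_us))
  invisible(x)
}

#' Chronological order of the benchmarked GROMOS parameter sets
#'
#' @return Character vector, oldest first.
#' @export
parameter_set_order <- function() c("45A4", "53A6", "54A7", "54A8")
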