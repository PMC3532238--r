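#' The p53-Mdm2 example network
#'
#' A two-gene independent PBN for the p53-Mdm2 damage-response circuit:
#' under DNA damage p53 promotes expression of Mdm2, which in turn drives
#' degradation of p53, producing the experimentally observed oscillation.
#' Each gene has four predictor functions on inputs (p53, Mdm2) with
#' selection probabilities (0.5, 0.4, 0.09, 0.01), for `N = 16`
#' constituent Boolean networks.
#'
#' @param perturbation Optional perturbation probability attached to the
#'   model (default 0).
#' @return A [pbn_model()] object.
#' @examples
#' round(transition_matrix_exact(fixture_p53_mdm2()), 4)
#' @export
fixture_p53_mdm2 <- function(perturbation = 0) {
  genes <- c("p53", "Mdm2")
  cs <- c(0.5, 0.4, 0.09, 0.01)
  ## truth columns over states 00, 01, 10, 11 (p53 bit varying slowest)
  t_p53  <- list(c(1, 1, 0, 0), c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, 0, 1, 1))
  t_mdm2 <- list(c(0, 0, 1, 1), c(0, 0, 1, 0), c(0, 1, 0, 0), c(1, 1, 0, 0))
  mk <- function(tabs) lapply(seq_along(tabs), function(j)
    pbn_function(genes, table = tabs[[j]], prob = cs[j]))
  pbn_model(genes, list(p53 = mk(t_p53), Mdm2 = mk(t_mdm2)),
            perturbation = perturbation)
}

#' Save / load a PBN as JSON
#'
#' The interchange format is a JSON object with fields `genes` (array),
#' `perturbation` (number), optional `periods` (array) and `functions`
#' (object mapping each gene to an array of
#' `{inputs, table | gate, prob}`). Probabilities are written at full
#' precision so that save -> load round-trips the model losslessly.
#'
#' @param model A [pbn_model()] object.
#' @param path File path.
#' @return `load_network()` returns a [pbn_model()]; `save_network()`
#'   returns `path` invisibly. Schema violations (missing fields, truth
#'   table length mismatches, selection probabilities not summing to 1)
#'   are rejected with a diagnostic naming the offending gene/field.
#' @export
save_network <- function(model, path) {
  stopifnot(inherits(model, "pbn"))
  obj <- list(
    genes = model$genes,
    perturbation = model$perturbation,
    periods = if (is.null(model$periods)) NULL else unname(model$periods),
    functions = lapply(model$functions, function(fs) lapply(fs, function(fn) {
      out <- list(inputs = fn$inputs, prob = fn$prob)
      if (!is.null(fn$gate)) out$gate <- fn$gate else out$table <- fn$table
      out
    }))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("genes", "functions"))
    if (is.null(obj[[field]]))
      stop(sprintf("network file %s: missing required field `%s`",
                   path, field))
  genes <- unname(vapply(obj$genes, as.character, character(1)))
  functions <- lapply(genes, function(g) {
    fs <- obj$functions[[g]]
    if (is.null(fs))
      stop(sprintf("network file %s: no functions for gene `%s`", path, g))
    lapply(seq_along(fs), function(j) {
      fn <- fs[[j]]
      if (is.null(fn$prob))
        stop(sprintf("gene `%s`, function %d: missing `prob`", g, j))
      if (is.null(fn$inputs))
        stop(sprintf("gene `%s`, function %d: missing `inputs`", g, j))
      inputs <- unname(vapply(fn$inputs, as.character, character(1)))
      if (!is.null(fn$gate)) {
        pbn_function(inputs, gate = fn$gate, prob = fn$prob)
      } else if (!is.null(fn$table)) {
        pbn_function(inputs, table = unlist(fn$table), prob = fn$prob)
      } else {
        stop(sprintf("gene `%s`, function %d: needs `table` or `gate`",
                     g, j))
      }
    })
  })
  names(functions) <- genes
  pbn_model(genes, functions,
            perturbation = if (is.null(obj$perturbation)) 0
                           else obj$perturbation,
            periods = if (is.null(obj$periods)) NULL
                      else unlist(obj$periods))
}

#' Gene coding of the T-cell immune response network
#'
#' The 12 meta-genes of the IL-2-stimulated T-cell (CTLL-2) network and
#' their symbols `g(1)...g(12)`; gene `i` contributes bit `2^(i-1)` to the
#' LSB-first 1-based state number (see [encode_state()], convention
#' `"eq10"`).
#'
#' @return A data frame with columns `symbol` and `gene`.
#' @export
tcell_genes <- function() {
  data.frame(
    symbol = sprintf("g(%d)", 1:12),
    gene = c("E-Jun-Fos", "L-Nsbp1", "L-Foxm1", "I-BIc3", "I-Myc",
             "L-Myb12", "E-Cdkn2c", "E-Stat1-6", "I-Rpol-hnr",
             "E-stat5a", "E-stat5b", "L-Mcmd"))
}

#' Load the T-cell PBN truth table
#'
#' Loads the 12-meta-gene PBN inferred from the IL-2-stimulated T-cell
#' microarray time series. The truth tables themselves are distributed as
#' supplementary material of the source study and are not bundled here;
#' the user must supply the file. Two layouts are accepted:
#'
#' * the JSON network format of [load_network()], with exactly the 12
#'   genes of [tcell_genes()] in order `g(1)...g(12)`;
#' * a TSV with columns `gene`, `prob`, `inputs` (comma-separated gene
#'   names) and `table` (a string of 0/1 characters, rows enumerating the
#'   inputs in binary with the first-listed input varying slowest), one
#'   row per predictor function.
#'
#' @param path Path to the supplementary truth-table file.
#' @return A 12-gene [pbn_model()] with gene order `g(1)...g(12)`.
#' @export
load_tcell_network <- function(path) {
  if (missing(path) || !file.exists(path))
    stop("the T-cell PBN truth table is not bundled with this package: ",
         "supply the supplementary data file ('Truth table of the PBN ",
         "inferred from the T cell microarray time series data') as ",
         "`path`, either in the JSON network format or as a TSV with ",
         "columns gene/prob/inputs/table")
  expected <- tcell_genes()$gene
  model <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    load_network(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    tab$prob <- as.numeric(tab$prob)
    need <- c("gene", "prob", "inputs", "table")
    if (!all(need %in% names(tab)))
      stop("T-cell truth-table TSV must have columns: ",
           paste(need, collapse = ", "))
    functions <- lapply(expected, function(g) {
      rows <- which(tab$gene == g)
      if (!length(rows))
        stop("T-cell truth table: no functions for gene ", g)
      lapply(rows, function(r) {
        ins <- trimws(strsplit(tab$inputs[r], ",")[[1]])
        bits <- as.integer(strsplit(tab$table[r], "")[[1]])
        pbn_function(ins, table = bits, prob = tab$prob[r])
      })
    })
    names(functions) <- expected
    pbn_model(expected, functions)
  }
  if (!identical(model$genes, expected))
    stop("T-cell network must contain exactly the 12 meta-genes in the ",
         "order g(1)...g(12): ", paste(expected, collapse = ", "))
  model
}

#' Write / read a transition matrix as TSV
#'
#' Matrices are written with a header row and a leading column of binary
#' state labels in the declared index convention; cells carry 6 decimals.
#'
#' @param A A transition matrix (or any square matrix over states).
#' @param path File path.
#' @param digits Decimals written (default 6).
#' @return `read_matrix_tsv()` returns the matrix with state labels;
#'   `write_matrix_tsv()` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(A, path, digits = 6) {
  labels <- rownames(A)
  if (is.null(labels)) labels <- state_labels(round(log2(nrow(A))))
  df <- data.frame(state = labels,
                   formatC(unclass(A), digits = digits, format = "f"),
                   check.names = FALSE)
  colnames(df) <- c("state", labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(state = "character"))
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$state
  storage.mode(A) <- "double"
  .tag_convention(A)
}
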