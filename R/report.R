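## Report export: tab-separated spreadsheet files plus a single
## self-contained static HTML page.  TSV is used as the spreadsheet
## format (diff-able, no binary-writer dependency); the HTML report
## carries the same membership lists, the size-vs-gamma summary and the
## pairwise intersections of the critical sets.

report_set_list <- function(report) {
  list(chokepoints = report$chokepoints,
       dead_end_metabolites = report$dead_end_metabolites,
       essential = report$essential,
       blocked = report$blocked,
       dead = report$partition$dead,
       reversible = report$partition$reversible,
       non_reversible = report$partition$non_reversible)
}

report_level_label <- function(report)
  if (is.na(report$gamma)) "baseline" else sprintf("gamma_%g", report$gamma)

#' Export a gamma sweep (and/or one report) as TSV and HTML
#'
#' Writes `summary.tsv` (set sizes per gamma, baseline row first),
#' `memberships.tsv` (long format: level, set, identifier) and
#' `report.html` (a static page with the summary table, one table per
#' set and level, and the pairwise intersection sizes of chokepoints,
#' essential, blocked and dead sets).
#'
#' @param result a `gamma_sweep` from [run_sweep()], or `NULL` when
#'   exporting a single report.
#' @param report optional extra `vulnerability_report` to include.
#' @param out_dir output directory, created if needed.
#' @param formats subset of `c("tsv", "html")`.
#' @return character vector of written file paths, invisibly.
#' @export
export_report <- function(result = NULL, report = NULL, out_dir,
                          formats = c("tsv", "html")) {
  formats <- match.arg(formats, c("tsv", "html"), several.ok = TRUE)
  if (is.null(result) && is.null(report))
    stop("provide a sweep result and/or a single report")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  reports <- list()
  sizes <- NULL
  if (!is.null(result)) {
    stopifnot(inherits(result, "gamma_sweep"))
    reports <- c(list(result$baseline), unname(result$reports))
    sizes <- result$sizes
  }
  if (!is.null(report)) {
    stopifnot(inherits(report, "vulnerability_report"))
    reports <- c(reports, list(report))
  }
  labels <- vapply(reports, report_level_label, character(1))
  dup <- !duplicated(labels)
  reports <- reports[dup]; labels <- labels[dup]

  long <- do.call(rbind, lapply(seq_along(reports), function(k) {
    sets <- report_set_list(reports[[k]])
    do.call(rbind, lapply(names(sets), function(nm) {
      ids <- sets[[nm]]
      if (!length(ids)) return(NULL)
      data.frame(level = labels[k], set = nm, id = ids,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(long))
    long <- data.frame(level = character(), set = character(),
                       id = character(), stringsAsFactors = FALSE)

  written <- character()
  if ("tsv" %in% formats) {
    p1 <- file.path(out_dir, "memberships.tsv")
    utils::write.table(long, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, p1)
    if (!is.null(sizes)) {
      p2 <- file.path(out_dir, "summary.tsv")
      utils::write.table(sizes, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, p2)
    }
  }
  if ("html" %in% formats) {
    p3 <- file.path(out_dir, "report.html")
    writeLines(render_html_report(reports, labels, sizes), p3)
    written <- c(written, p3)
  }
  invisible(written)
}

html_table <- function(df) {
  if (!nrow(df)) return("<p><em>empty</em></p>")
  head <- paste0("<tr>", paste0("<th>", xml_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(df, 1, function(row)
    paste0("<tr>", paste0("<td>", xml_escape(as.character(row)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

render_html_report <- function(reports, labels, sizes) {
  out <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
           "<title>Metabolic vulnerability report</title>",
           "<style>body{font-family:sans-serif;margin:2em}",
           "table{border-collapse:collapse;margin:1em 0}",
           "td,th{border:1px solid #999;padding:2px 8px;text-align:left}",
           "h2{border-bottom:1px solid #ccc}</style></head><body>",
           "<h1>Metabolic vulnerability report</h1>")
  if (!is.null(sizes)) {
    out <- c(out, "<h2>Set sizes per growth fraction</h2>",
             html_table(sizes))
  }
  crit <- c("chokepoints", "essential", "blocked", "dead")
  for (k in seq_along(reports)) {
    sets <- report_set_list(reports[[k]])
    out <- c(out, sprintf("<h2>Level: %s</h2>", xml_escape(labels[k])))
    for (nm in names(sets)) {
      ids <- sets[[nm]]
      out <- c(out, sprintf("<h3>%s (%d)</h3>", nm, length(ids)),
               if (length(ids))
                 paste0("<p class='ids' data-set='", nm, "'>",
                        paste(xml_escape(ids), collapse = ", "), "</p>")
               else "<p><em>empty</em></p>")
    }
    ## pairwise intersections of the critical sets
    inter <- expand.grid(a = crit, b = crit, stringsAsFactors = FALSE)
    inter <- inter[inter$a < inter$b, ]
    inter$size <- mapply(function(a, b)
      length(intersect(sets[[a]], sets[[b]])), inter$a, inter$b)
    out <- c(out, "<h3>Set intersections</h3>", html_table(inter))
  }
  c(out, "</body></html>")
}
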