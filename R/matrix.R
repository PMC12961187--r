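#' Sample manifest
#'
#' Declares the role of every sequencing library: a regular sample
#' (optionally in a replicate group), a positive control or a negative
#' control.
#'
#' @param sample_id character vector of unique ids.
#' @param role one of `"sample"`, `"positive_control"`,
#'   `"negative_control"` per sample.
#' @param replicate_group group label for replicated samples (`NA`
#'   otherwise; only allowed on `role = "sample"`).
#' @return data.frame of class `mb_manifest`.
#' @export
sample_manifest <- function(sample_id,
                            role = rep("sample", length(sample_id)),
                            replicate_group = rep(NA_character_,
                                                  length(sample_id))) {
    role <- match.arg(role, c("sample", "positive_control",
                              "negative_control"), several.ok = TRUE)
    if (anyDuplicated(sample_id)) stop("sample ids must be unique")
    if (any(!is.na(replicate_group) & role != "sample"))
        stop("replicate_group is only allowed on role = 'sample'")
    structure(data.frame(sample_id = sample_id, role = role,
                         replicate_group = replicate_group,
                         stringsAsFactors = FALSE),
              class = c("mb_manifest", "data.frame"))
}

#' Read a sample manifest TSV (sample_id, role, replicate_group)
#' @param path file path.
#' @return an `mb_manifest`.
#' @export
read_manifest <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                     stringsAsFactors = FALSE, na.strings = c("", "NA"))
    sample_manifest(df$sample_id, df$role, df$replicate_group)
}

#' Assemble the species-by-sample result matrix with P/N/S badges
#'
#' Columns follow the manifest order; rows are the species / species-complex
#' labels. Badges: `P` -- detected in at least one positive control; `N` --
#' detected in at least one negative control; `S` -- present in only a
#' single replicate: exactly one detection among the replicate columns
#' (groups of size >= 2) and none in any other sample column
#' (`single_replicate_scope = "global"`, the default) or, with `"group"`,
#' exactly one detection within some group and none in any other sample
#' column. Detection means count > `min_reads` (default 0).
#'
#' @param species_table the `species` data.frame from [summarize_tables()]
#'   (columns `label`, `members` list column, one count column per sample).
#' @param manifest an `mb_manifest`; every count column must appear in it.
#' @param min_reads detection threshold (default 0: any read detects).
#' @param single_replicate_scope `"global"` or `"group"`.
#' @return object of class `mb_matrix`: `labels`, `members`, `counts`
#'   (rows x manifest samples), `badges` (list of character subsets of
#'   P/N/S), `manifest`.
#' @export
build_matrix <- function(species_table, manifest, min_reads = 0,
                         single_replicate_scope = c("global", "group")) {
    single_replicate_scope <- match.arg(single_replicate_scope)
    stopifnot(inherits(manifest, "mb_manifest"))
    res_samples <- setdiff(names(species_table),
                           c("label", "members", "best_identity", "notes"))
    missing <- setdiff(res_samples, manifest$sample_id)
    if (length(missing) > 0L)
        stop("results reference samples absent from the manifest: ",
             paste(missing, collapse = ", "))
    n <- nrow(species_table)
    counts <- matrix(0L, nrow = n, ncol = nrow(manifest),
                     dimnames = list(NULL, manifest$sample_id))
    for (s in res_samples)
        counts[, s] <- as.integer(species_table[[s]])
    detected <- counts > min_reads
    pos <- manifest$role == "positive_control"
    neg <- manifest$role == "negative_control"
    grp <- manifest$replicate_group
    grp_sizes <- table(grp[!is.na(grp)])
    in_rep <- !is.na(grp) & grp %in% names(grp_sizes)[grp_sizes >= 2]
    plain <- manifest$role == "sample" & !in_rep
    badges <- lapply(seq_len(n), function(i) {
        b <- character(0)
        if (any(detected[i, pos])) b <- c(b, "P")
        if (any(detected[i, neg])) b <- c(b, "N")
        s_badge <- if (single_replicate_scope == "global") {
            sum(detected[i, in_rep]) == 1L && !any(detected[i, plain])
        } else {
            hits_per_group <- tapply(detected[i, in_rep], grp[in_rep], sum)
            any(hits_per_group == 1L) && sum(detected[i, in_rep]) == 1L &&
                !any(detected[i, plain])
        }
        if (any(in_rep) && s_badge) b <- c(b, "S")
        b
    })
    structure(list(labels = species_table$label,
                   members = if (!is.null(species_table$members))
                       species_table$members
                   else as.list(species_table$label),
                   counts = counts, badges = badges, manifest = manifest),
              class = "mb_matrix")
}

#' Filter rows (or complex members) of a result matrix
#'
#' Applies a row predicate and/or a member-level predicate. The row
#' predicate receives a list with `label`, `members`, `badges` and the
#' named count vector and must return `TRUE` to keep the row. The member
#' predicate receives the member species names and returns a logical
#' vector; complexes shrink to the passing members (rows with none left are
#' dropped) and labels are rebuilt. Filtering is never applied
#' automatically and the input matrix is unchanged.
#'
#' @param m an `mb_matrix`.
#' @param predicate row predicate function or `NULL`.
#' @param member_filter member predicate function or `NULL`.
#' @return a new `mb_matrix`.
#' @export
filter_matrix <- function(m, predicate = NULL, member_filter = NULL) {
    stopifnot(inherits(m, "mb_matrix"))
    keep <- rep(TRUE, length(m$labels))
    members <- m$members
    labels <- m$labels
    if (!is.null(member_filter)) {
        for (i in seq_along(members)) {
            ok <- member_filter(members[[i]])
            members[[i]] <- members[[i]][ok]
            if (length(members[[i]]) == 0L) keep[i] <- FALSE
            else labels[i] <- complex_label(members[[i]])
        }
    }
    if (!is.null(predicate)) {
        for (i in seq_along(labels)) {
            if (!keep[i]) next
            row <- list(label = labels[i], members = members[[i]],
                        badges = m$badges[[i]], counts = m$counts[i, ])
            keep[i] <- isTRUE(predicate(row))
        }
    }
    structure(list(labels = labels[keep], members = members[keep],
                   counts = m$counts[keep, , drop = FALSE],
                   badges = m$badges[keep], manifest = m$manifest),
              class = "mb_matrix")
}

#' Export / import a result matrix as CSV
#'
#' The CSV has a `taxon` column (the species / complex label), a `badges`
#' column (semicolon-joined subset of P/N/S) and one column per sample in
#' manifest order. `parse_matrix_csv` inverts `export_csv` losslessly for
#' counts and badges.
#'
#' @param m an `mb_matrix`.
#' @param path file to write (or read). `export_csv` with `path = NULL`
#'   returns the CSV text invisibly without writing.
#' @return `export_csv` the CSV text (invisibly when writing);
#'   `parse_matrix_csv` an `mb_matrix` (with a plain-sample manifest
#'   reconstructed from the header).
#' @export
export_csv <- function(m, path = NULL) {
    stopifnot(inherits(m, "mb_matrix"))
    df <- data.frame(taxon = m$labels,
                     badges = vapply(m$badges, paste, "", collapse = ";"),
                     m$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    txt <- paste(out, collapse = "\n")
    if (!is.null(path)) writeLines(txt, path)
    invisible(txt)
}

#' @rdname export_csv
#' @export
parse_matrix_csv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
    samples <- setdiff(names(df), c("taxon", "badges"))
    counts <- as.matrix(df[, samples, drop = FALSE])
    storage.mode(counts) <- "integer"
    rownames(counts) <- NULL
    badges <- lapply(df$badges, function(b)
        if (nzchar(b)) strsplit(b, ";", fixed = TRUE)[[1]] else character(0))
    structure(list(labels = df$taxon,
                   members = lapply(df$taxon, function(l)
                       strsplit(l, "/", fixed = TRUE)[[1]]),
                   counts = counts, badges = badges,
                   manifest = sample_manifest(samples)),
              class = "mb_matrix")
}

#' Compare detected taxa with a published taxon list
#'
#' Categorizes every published taxon into one of five classes:
#' \describe{
#'   \item{Single}{resolved to species level, consistent with the
#'     publication (for a published clade: the resolved species belongs to
#'     it);}
#'   \item{Multiple}{resolved to a species complex containing (or nested
#'     under) the published taxon;}
#'   \item{Clades}{resolved to a matching higher taxon;}
#'   \item{Diff}{present but as a different taxon (approximated as: a
#'     congeneric species was detected instead);}
#'   \item{Undetected}{no related row in the results.}
#' }
#' Each published taxon receives exactly one category.
#'
#' @param tables result tables from [summarize_tables()] (elements
#'   `species` and `higher` are used).
#' @param published data.frame with columns `taxon` and `level`
#'   (`"species"` or `"clade"`).
#' @param taxonomy taxonomy table ([taxonomy_table()]).
#' @return `published` with an added `category` column.
#' @export
compare_to_published <- function(tables, published, taxonomy) {
    members <- tables$species$members
    single <- unlist(members[lengths(members) == 1L])
    multi <- unique(unlist(members[lengths(members) >= 2L]))
    all_members <- unique(unlist(members))
    higher <- unique(tables$higher$taxon)
    ancestors <- function(sp) {
        i <- match(sp, taxonomy$species)
        if (is.na(i)) return(sub(" .*$", "", sp))
        unique(c(taxonomy$genus[i], taxonomy$family[i], taxonomy$order[i]))
    }
    genus_of <- function(sp) sub(" .*$", "", sp)
    category <- vapply(seq_len(nrow(published)), function(k) {
        tx <- published$taxon[k]
        if (published$level[k] == "species") {
            if (tx %in% single) return("Single")
            if (tx %in% multi) return("Multiple")
            if (any(ancestors(tx) %in% higher)) return("Clades")
            if (any(genus_of(all_members) == genus_of(tx))) return("Diff")
            return("Undetected")
        }
        # published clade
        under <- vapply(all_members, function(sp) tx %in% ancestors(sp),
                        logical(1))
        if (any(under[all_members %in% single])) return("Single")
        if (any(under[all_members %in% multi])) return("Multiple")
        if (tx %in% higher) return("Clades")
        if (any(under)) return("Diff")
        "Undetected"
    }, character(1))
    out <- published
    out$category <- category
    out
}
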