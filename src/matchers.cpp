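// Core sequence matchers:
//  - scan_reads_te_cpp: ungapped seed-and-extend matching of short reads
//    against a TE sequence (both orientations, dense 1-nt seeding).
//  - align_ungapped_cpp: exhaustive ungapped placement of short (trimmed)
//    reads on a reference, reporting the best mismatch count and the number
//    of equally good placements (uniqueness filter).
//  - align_gapped_cpp: seeded, banded gapped alignment of whole reads for
//    spanner counting and excision-footprint detection.
// Conventions: all returned coordinates are 1-based inclusive; 'N' never
// matches any base.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <set>
#include <string>
#include <vector>
#include <tuple>
#include <cstdint>

using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) c = comp_base(c);
    return r;
}

// N is a mismatch against everything, including itself
static inline bool base_eq(char a, char b) {
    return a == b && a != 'N';
}

// [[Rcpp::export]]
DataFrame scan_reads_te_cpp(CharacterVector seqs, std::string te,
                            int seed_len, int min_aligned, double allowance) {
    const int tlen = (int) te.size();
    std::unordered_map<std::string, std::vector<int>> idx;
    for (int j = 0; j + seed_len <= tlen; ++j) {
        std::string s = te.substr(j, seed_len);
        if (s.find('N') != std::string::npos) continue;
        idx[s].push_back(j);
    }

    std::vector<int> o_read, o_rs, o_re, o_ts, o_te, o_mm, o_len;
    std::vector<std::string> o_strand;

    for (int ri = 0; ri < seqs.size(); ++ri) {
        const std::string fwd = as<std::string>(seqs[ri]);
        const int L = (int) fwd.size();
        if (L < seed_len) continue;
        for (int strand = 0; strand < 2; ++strand) {
            const std::string r = strand ? revcomp_str(fwd) : fwd;
            // per-diagonal windows already reported (0-based half-open on r)
            std::unordered_map<long long, std::vector<std::pair<int, int>>> seen;
            for (int i = 0; i + seed_len <= L; ++i) {
                auto it = idx.find(r.substr(i, seed_len));
                if (it == idx.end()) continue;
                for (int j : it->second) {
                    const long long d = (long long) j - i;
                    auto &wins = seen[d];
                    bool covered = false;
                    for (auto &w : wins)
                        if (i >= w.first && i + seed_len <= w.second) { covered = true; break; }
                    if (covered) continue;

                    // maximal ungapped extension: mismatches are extended
                    // through as long as the FINAL mismatch fraction of the
                    // committed window stays within the allowance
                    // (lookahead-and-commit, alternating directions)
                    int rs = i, re = i + seed_len, ts = j;
                    int mm = 0;
                    bool grew = true;
                    while (grew) {
                        grew = false;
                        // rightward lookahead
                        int cur = mm, best_re = re, best_mm = mm;
                        for (int e = re; e < L && ts + (e - rs) < tlen; ++e) {
                            if (!base_eq(r[e], te[ts + (e - rs)])) ++cur;
                            const int len2 = e + 1 - rs;
                            if ((double) cur / len2 <= allowance) {
                                best_re = e + 1; best_mm = cur;
                            }
                        }
                        if (best_re != re) { re = best_re; mm = best_mm; grew = true; }
                        // leftward lookahead
                        cur = mm; int best_rs = rs; best_mm = mm;
                        for (int s = rs - 1; s >= 0 && ts - (rs - s) >= 0; --s) {
                            if (!base_eq(r[s], te[ts - (rs - s)])) ++cur;
                            const int len2 = re - s;
                            if ((double) cur / len2 <= allowance) {
                                best_rs = s; best_mm = cur;
                            }
                        }
                        if (best_rs != rs) {
                            ts -= rs - best_rs; rs = best_rs; mm = best_mm;
                            grew = true;
                        }
                    }
                    const int len = re - rs;
                    wins.push_back(std::make_pair(rs, re));
                    if (len < min_aligned) continue;
                    if ((double) mm / len > allowance) continue;

                    int frs, fre;              // 1-based inclusive on the input read
                    if (!strand) { frs = rs + 1; fre = re; }
                    else         { frs = L - re + 1; fre = L - rs; }
                    o_read.push_back(ri + 1);
                    o_rs.push_back(frs);  o_re.push_back(fre);
                    o_ts.push_back(ts + 1); o_te.push_back(ts + len);
                    o_mm.push_back(mm);   o_len.push_back(len);
                    o_strand.push_back(strand ? "-" : "+");
                }
            }
        }
    }
    return DataFrame::create(
        _["read"] = o_read, _["r_start"] = o_rs, _["r_end"] = o_re,
        _["t_start"] = o_ts, _["t_end"] = o_te, _["strand"] = o_strand,
        _["mismatches"] = o_mm, _["aligned_len"] = o_len,
        _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame align_ungapped_cpp(CharacterVector seqs, CharacterVector genome,
                             int max_mismatch) {
    const int nch = (int) genome.size();
    std::vector<std::string> chroms(nch);
    for (int c = 0; c < nch; ++c) chroms[c] = as<std::string>(genome[c]);

    const int n = (int) seqs.size();
    IntegerVector o_chrom(n), o_pos(n), o_mm(n), o_nbest(n);
    CharacterVector o_strand(n);

    for (int ri = 0; ri < n; ++ri) {
        const std::string fwd = as<std::string>(seqs[ri]);
        const int L = (int) fwd.size();
        int best = max_mismatch + 1, nbest = 0, bchrom = -1, bpos = -1, bstrand = 0;
        for (int strand = 0; strand < 2; ++strand) {
            const std::string r = strand ? revcomp_str(fwd) : fwd;
            for (int c = 0; c < nch; ++c) {
                const std::string &g = chroms[c];
                const int G = (int) g.size();
                for (int p = 0; p + L <= G; ++p) {
                    int mm = 0;
                    for (int i = 0; i < L; ++i) {
                        if (!base_eq(r[i], g[p + i])) { if (++mm > best) break; }
                    }
                    if (mm < best) {
                        best = mm; nbest = 1; bchrom = c; bpos = p; bstrand = strand;
                    } else if (mm == best && best <= max_mismatch) {
                        ++nbest;
                    }
                }
            }
        }
        if (nbest == 0 || best > max_mismatch) {
            o_chrom[ri] = NA_INTEGER; o_pos[ri] = NA_INTEGER;
            o_mm[ri] = NA_INTEGER; o_nbest[ri] = 0; o_strand[ri] = NA_STRING;
        } else {
            o_chrom[ri] = bchrom + 1; o_pos[ri] = bpos + 1;
            o_mm[ri] = best; o_nbest[ri] = nbest;
            o_strand[ri] = bstrand ? "-" : "+";
        }
    }
    return DataFrame::create(
        _["chrom"] = o_chrom, _["pos"] = o_pos, _["strand"] = o_strand,
        _["mismatches"] = o_mm, _["n_best"] = o_nbest,
        _["stringsAsFactors"] = false);
}

// ---- gapped whole-read aligner ------------------------------------------

static inline bool encode_kmer(const std::string &s, int pos, int k, uint64_t &out) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int b;
        switch (s[pos + i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: return false;
        }
        v = (v << 2) | (uint64_t) b;
    }
    out = v;
    return true;
}

struct Placement { int edit; std::string cigar; };

// CIGAR with =/X ops for an ungapped placement of r at g[s0..]
static std::string ungapped_cigar(const std::string &r, const std::string &g,
                                  int s0) {
    std::string cg;
    char cur = 0;
    int run = 0;
    for (int i = 0; i < (int) r.size(); ++i) {
        const char op = base_eq(r[i], g[s0 + i]) ? '=' : 'X';
        if (op == cur) ++run;
        else {
            if (run) cg += std::to_string(run) + cur;
            cur = op; run = 1;
        }
    }
    if (run) cg += std::to_string(run) + cur;
    return cg;
}

// banded-ish semi-global alignment of read r against ref window g
// (free leading/trailing ref); returns edit distance, CIGAR and the 0-based
// start of the alignment inside g.  Full DP over the (small) window.
static bool dp_align(const std::string &r, const std::string &g,
                     int &edit, std::string &cigar, int &gstart) {
    const int L = (int) r.size(), Gw = (int) g.size();
    if (Gw == 0) return false;
    std::vector<std::vector<int>> dp(L + 1, std::vector<int>(Gw + 1));
    for (int j = 0; j <= Gw; ++j) dp[0][j] = 0;
    for (int i = 1; i <= L; ++i) {
        dp[i][0] = i;
        for (int j = 1; j <= Gw; ++j) {
            const int sub = dp[i - 1][j - 1] + (base_eq(r[i - 1], g[j - 1]) ? 0 : 1);
            const int ins = dp[i - 1][j] + 1;   // read base not in ref (I)
            const int del = dp[i][j - 1] + 1;   // ref base not in read (D)
            int v = sub;
            if (ins < v) v = ins;
            if (del < v) v = del;
            dp[i][j] = v;
        }
    }
    int jbest = 0, best = dp[L][0];
    for (int j = 1; j <= Gw; ++j)
        if (dp[L][j] < best) { best = dp[L][j]; jbest = j; }
    // traceback, prefer diagonal, then D, then I (deterministic)
    std::vector<std::pair<char, int>> ops;
    int i = L, j = jbest;
    auto push_op = [&ops](char op) {
        if (!ops.empty() && ops.back().first == op) ops.back().second++;
        else ops.push_back(std::make_pair(op, 1));
    };
    while (i > 0) {
        if (j > 0 && dp[i][j] == dp[i - 1][j - 1] + (base_eq(r[i - 1], g[j - 1]) ? 0 : 1)) {
            push_op(base_eq(r[i - 1], g[j - 1]) ? '=' : 'X'); --i; --j;
        } else if (j > 0 && dp[i][j] == dp[i][j - 1] + 1) {
            push_op('D'); --j;
        } else {
            push_op('I'); --i;
        }
    }
    std::string cg;
    for (auto it = ops.rbegin(); it != ops.rend(); ++it)
        cg += std::to_string(it->second) + it->first;
    edit = best; cigar = cg; gstart = j;
    return true;
}

// [[Rcpp::export]]
DataFrame align_gapped_cpp(CharacterVector seqs, CharacterVector genome,
                           int kmer, int band, int max_edit) {
    const int nch = (int) genome.size();
    std::vector<std::string> chroms(nch);
    for (int c = 0; c < nch; ++c) chroms[c] = as<std::string>(genome[c]);

    // reference k-mer index
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
    for (int c = 0; c < nch; ++c) {
        const std::string &g = chroms[c];
        for (int p = 0; p + kmer <= (int) g.size(); ++p) {
            uint64_t v;
            if (encode_kmer(g, p, kmer, v))
                idx[v].push_back(std::make_pair(c, p));
        }
    }

    const int n = (int) seqs.size();
    IntegerVector o_chrom(n), o_pos(n), o_edit(n), o_nbest(n);
    CharacterVector o_strand(n), o_cigar(n);

    for (int ri = 0; ri < n; ++ri) {
        const std::string fwd = as<std::string>(seqs[ri]);
        const int L = (int) fwd.size();
        // best placements keyed by (chrom, strand, refstart0)
        std::map<std::tuple<int, int, int>, Placement> placements;

        for (int strand = 0; strand < 2; ++strand) {
            const std::string r = strand ? revcomp_str(fwd) : fwd;
            if (L < kmer) continue;
            std::set<int> offs = {0, (L - kmer) / 3, 2 * (L - kmer) / 3, L - kmer};
            std::set<std::pair<int, int>> cands;   // (chrom, cand start0)
            for (int o : offs) {
                if (o < 0 || o + kmer > L) continue;
                uint64_t v;
                if (!encode_kmer(r, o, kmer, v)) continue;
                auto it = idx.find(v);
                if (it == idx.end()) continue;
                if ((int) it->second.size() > 5000) continue;  // uninformative seed
                for (auto &hit : it->second)
                    cands.insert(std::make_pair(hit.first, hit.second - o));
            }
            for (auto &cd : cands) {
                const int c = cd.first, s0 = cd.second;
                const std::string &g = chroms[c];
                const int G = (int) g.size();
                // ungapped evaluation first
                int mm = -1;
                if (s0 >= 0 && s0 + L <= G) {
                    mm = 0;
                    for (int i = 0; i < L; ++i) {
                        if (!base_eq(r[i], g[s0 + i])) { if (++mm > max_edit) break; }
                    }
                }
                if (mm >= 0 && mm <= 2) {
                    auto key = std::make_tuple(c, strand, s0);
                    auto f = placements.find(key);
                    if (f == placements.end() || f->second.edit > mm)
                        placements[key] = Placement{mm, ungapped_cigar(r, g, s0)};
                    continue;
                }
                // banded gapped alignment around the candidate
                const int ws = std::max(0, s0 - band);
                const int we = std::min(G, s0 + L + band);
                if (we - ws < kmer) continue;
                int edit, gstart;
                std::string cg;
                if (!dp_align(r, g.substr(ws, we - ws), edit, cg, gstart)) continue;
                if (mm >= 0 && mm <= max_edit && mm < edit) {
                    edit = mm; cg = ungapped_cigar(r, g, s0); gstart = s0 - ws;
                }
                if (edit > max_edit) continue;
                auto key = std::make_tuple(c, strand, ws + gstart);
                auto f = placements.find(key);
                if (f == placements.end() || f->second.edit > edit)
                    placements[key] = Placement{edit, cg};
            }
        }

        int best = max_edit + 1, nbest = 0;
        std::tuple<int, int, int> bkey;
        for (auto &kv : placements) {
            if (kv.second.edit < best) { best = kv.second.edit; nbest = 1; bkey = kv.first; }
            else if (kv.second.edit == best) ++nbest;
        }
        if (nbest == 0) {
            o_chrom[ri] = NA_INTEGER; o_pos[ri] = NA_INTEGER;
            o_edit[ri] = NA_INTEGER; o_nbest[ri] = 0;
            o_strand[ri] = NA_STRING; o_cigar[ri] = NA_STRING;
        } else {
            o_chrom[ri] = std::get<0>(bkey) + 1;
            o_strand[ri] = std::get<1>(bkey) ? "-" : "+";
            o_pos[ri] = std::get<2>(bkey) + 1;
            o_edit[ri] = best; o_nbest[ri] = nbest;
            o_cigar[ri] = placements[bkey].cigar;
        }
    }
    return DataFrame::create(
        _["chrom"] = o_chrom, _["pos"] = o_pos, _["strand"] = o_strand,
        _["cigar"] = o_cigar, _["edit"] = o_edit, _["n_best"] = o_nbest,
        _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i)
        out[i] = revcomp_str(as<std::string>(seqs[i]));
    return out;
}
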