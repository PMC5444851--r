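# Converted per-population genotyping tables

Two acceptance-level tests recompute the published per-population mean
crossover counts and KL interference indices. They need the study's
per-population genotyping workbooks (XLSX, distributed with the article),
converted to the canonical TSV with `convert_supplementary_xlsx()` and
placed here before the package is installed:

    female_ArAr.tsv      female diploid ArAr'
    female_ArArCo.tsv    female allotriploid ArAr'Co
    female_AnAr.tsv      female diploid AnAr'
    female_AnArCn.tsv    female allotriploid AnAr'Cn
    male_AnAr.tsv        male diploid AnAr'
    male_AnArCn.tsv      male allotriploid AnAr'Cn

Each TSV: columns `marker_id`, `chrom`, `pos_bp`, then one column per
progeny with codes A/B/NA. The tables are not redistributed with the
package; without them those two tests report a failure stating that the
published quantities cannot be recomputed.
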