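mirbase_id,strand,overlap,evidence,gene_id,transcript_id,probeset_id,chromosome,start,end,mir,mir_star
hsa-let-7a-3,+,exon,HGNC_automatic_transcript,ENSG00000197182,ENST00000360737,232480_at;3948921,22,46449741,46509808,hsa-let-7a,hsa-let-7a*
hsa-let-7a-3,+,exon,Vega_transcript,ENSG00000197182,ENST00000360737,232480_at;3948949,22,46449741,46509808,hsa-let-7a,hsa-let-7a*
hsa-let-7b,+,exon,HGNC_automatic_transcript,ENSG00000197182,ENST00000360737,232480_at;3948921,22,46449741,46509808,hsa-let-7b,hsa-let-7b*
hsa-let-7b,+,exon,Vega_transcript,ENSG00000197182,ENST00000360737,232480_at;3948949,22,46449741,46509808,hsa-let-7b,hsa-let-7b*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915214,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915194,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915317,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915201,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915291,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915202,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915257,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_curated_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915275,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,HGNC_automatic_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915192,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,Vega_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915318,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,Vega_transcript,ENSG00000215386,ENST00000308787,1559901_s_at;3915193,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
hsa-let-7c,+,intron,Vega_transcript,ENSG00000215386,ENST00000400178,1559901_s_at;3915214,21,17442842,17982094,hsa-let-7c,hsa-let-7c*
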