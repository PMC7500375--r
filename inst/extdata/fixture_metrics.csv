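"participant","group","index","object","tms_condition","order_pair","analyzable","raw_estimate","dropped","multiple_lifts","tms_failed","not_lifted","t_liftoff","t_liftoff_truth","peak_LFR","peak_GFR","peak1_LFR","peak1_GFR","tp_LFR","tp_GFR","gf_static"
1,"aIPS",1,"heavy","dynamic","undefined",FALSE,14.6258633433809,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
1,"aIPS",2,"heavy","dynamic","HH",TRUE,14.6258633433809,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
1,"aIPS",3,"light","none","HL",TRUE,5.95546362602354,FALSE,FALSE,FALSE,FALSE,0.515,0.515,45.0550142994692,58.5712746242701,45.0550142994692,58.5712746242701,0.179,0.179,3.31942500000018
1,"aIPS",4,"heavy","none","LH",TRUE,14.9510033327818,FALSE,FALSE,FALSE,FALSE,0.966,0.965,37.545604653284,48.8092860492677,15.4415128233524,20.0739083383945,0.543,0.543,8.67568500000014
1,"aIPS",5,"light","static","HL",TRUE,5.95546362602354,FALSE,FALSE,FALSE,FALSE,0.515,0.515,45.0550142994692,58.5712746242701,45.0550142994692,58.5712746242701,0.179,0.179,3.31942500000018
1,"aIPS",6,"light","none","LL",TRUE,6.28060361542444,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
1,"aIPS",7,"medium","dynamic","undefined",FALSE,10.6570910918048,FALSE,FALSE,FALSE,FALSE,0.915,0.914,25.2494567192851,32.8242937350689,15.4415128257122,11.7268416143414,0.517,0.517,6.02306100000048
1,"aIPS",8,"light","dynamic","undefined",FALSE,6.11648533506018,FALSE,FALSE,FALSE,FALSE,0.541,0.541,29.9959127422249,38.9944693231106,29.9959127422249,38.9944693231106,0.18,0.18,3.31942500000019
1,"aIPS",9,"light","dynamic","LL",TRUE,6.28060361542444,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
1,"aIPS",10,"heavy","static","LH",TRUE,14.9510033327818,FALSE,FALSE,FALSE,FALSE,0.966,0.965,37.545604653284,48.8092860492677,15.4415128233524,20.0739083383945,0.543,0.543,8.67568500000014
1,"aIPS",11,"heavy","none","HH",TRUE,14.6258633433809,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
1,"aIPS",12,"light","dynamic","HL",TRUE,5.95546362602354,FALSE,FALSE,FALSE,FALSE,0.515,0.515,45.0550142994692,58.5712746242701,45.0550142994692,58.5712746242701,0.179,0.179,3.31942500000018
1,"aIPS",13,"light","static","LL",TRUE,6.28060361542444,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
1,"aIPS",14,"heavy","dynamic","LH",TRUE,14.9510033327818,FALSE,FALSE,FALSE,FALSE,0.966,0.965,37.545604653284,48.8092860492677,15.4415128233524,20.0739083383945,0.543,0.543,8.67568500000014
1,"aIPS",15,"heavy","static","HH",TRUE,14.6258633433809,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
2,"LO",1,"light","none","undefined",FALSE,4.37627667546962,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
2,"LO",2,"heavy","dynamic","LH",TRUE,11.7833244994845,FALSE,FALSE,FALSE,FALSE,0.966,0.965,37.545604653284,48.8092860492677,15.4415128233524,20.0739083383945,0.543,0.543,8.67568500000014
2,"LO",3,"light","none","HL",TRUE,4.09851238206905,FALSE,FALSE,FALSE,FALSE,0.515,0.515,45.0550142994692,58.5712746242701,45.0550142994692,58.5712746242701,0.179,0.179,3.31942500000018
2,"LO",4,"light","dynamic","LL",TRUE,4.37627667546962,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
2,"LO",5,"heavy","static","LH",TRUE,11.7833244994845,FALSE,FALSE,FALSE,FALSE,0.966,0.965,37.545604653284,48.8092860492677,15.4415128233524,20.0739083383945,0.543,0.543,8.67568500000014
2,"LO",6,"heavy","dynamic","HH",TRUE,11.505560206084,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
2,"LO",7,"light","static","HL",TRUE,4.09851238206905,FALSE,FALSE,FALSE,FALSE,0.515,0.515,45.0550142994692,58.5712746242701,45.0550142994692,58.5712746242701,0.179,0.179,3.31942500000018
2,"LO",8,"light","none","LL",TRUE,4.37627667546962,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
2,"LO",9,"heavy","none","LH",TRUE,11.7833244994845,FALSE,FALSE,FALSE,FALSE,0.966,0.965,37.545604653284,48.8092860492677,15.4415128233524,20.0739083383945,0.543,0.543,8.67568500000014
2,"LO",10,"medium","static","undefined",FALSE,7.83730795038135,FALSE,FALSE,FALSE,FALSE,0.563,0.563,44.2440585944475,57.5169433409495,44.2440585944475,57.5169433409495,0.176,0.176,6.02306100000049
2,"LO",11,"heavy","static","undefined",FALSE,11.6431196656728,FALSE,FALSE,FALSE,FALSE,0.861,0.86,35.5245454013309,46.1819090217284,29.985938296073,38.9814758198554,0.473,0.473,8.67568500000017
2,"LO",12,"heavy","static","HH",TRUE,11.505560206084,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
2,"LO",13,"heavy","none","HH",TRUE,11.505560206084,FALSE,FALSE,FALSE,FALSE,0.63,0.63,44.2556189561727,57.5319718111955,44.2556189561727,57.5319718111955,0.176,0.176,8.67568500000014
2,"LO",14,"light","dynamic","HL",TRUE,4.09851238206905,FALSE,FALSE,FALSE,FALSE,0.515,0.515,45.0550142994692,58.5712746242701,45.0550142994692,58.5712746242701,0.179,0.179,3.31942500000018
2,"LO",15,"light","static","LL",TRUE,4.37627667546962,FALSE,FALSE,FALSE,FALSE,0.624,0.624,15.441515182261,20.0739114049759,15.441515182261,11.7268416144582,0.188,0.188,3.3194250000002
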